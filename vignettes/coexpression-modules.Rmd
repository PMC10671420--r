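---
title: "Co-expression modules and candidate-gene prioritization: methods"
author: "coexmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-expression modules and candidate-gene prioritization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexmod)
```

# Scope and model

`coexmod` analyzes a genes × samples expression matrix in RPKM units — the
reference dialect is a BrainSpan-style developmental brain transcriptome —
together with curated gene lists for neurological phenotypes (ASD,
intellectual disability, seizures, hypotonia, language impairment) and a
chromosome-region list (22q13, the Phelan–McDermid deletion region). The
analysis assumes that genes sharing expression dynamics across brain
development share function ("guilt by association"): a region gene that
co-expresses tightly with many known ASD genes is a candidate contributor to
the ASD phenotype of the deletion.

The pipeline is the weighted co-expression network workflow:

1. **Preprocessing.** Genes summing to 0 RPKM are removed, values are
   log2(RPKM + 1) transformed, and genes with mean expression below 0.3 RPKM
   are filtered. The mean is always taken on the RPKM scale, computed before
   the transform and carried on the matrix object, so the filter's meaning
   does not depend on call order; the boundary (mean exactly 0.3) is kept,
   reading the rule as "remove < 0.3". Sample outliers are flagged by
   average-linkage clustering of samples on Euclidean distance (singletons
   above the 0.95 merge-height quantile) but never removed: outlier handling
   is a reporting concern, removal is the analyst's decision. Missing values
   are a hard error — RPKM matrices are dense, and silent imputation would
   change the correlation structure invisibly.
2. **Network.** Pearson similarity s = |cor| (unsigned; see *Design
   decisions*), adjacency a = s^β, topological overlap
   TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij) with the diagonal
   excluded from the connectivity and shared-neighbor sums, and dissimilarity
   1 − TOM.
3. **Soft threshold.** β is scanned over 1..20; for each candidate the
   connectivity vector is binned into 10 equal-width bins and
   log10(frequency) is regressed on log10(bin center) over non-empty bins.
   The fit R² is signed by the negative slope sign so that only a
   *decreasing* connectivity distribution counts as scale-free; the smallest
   β with signed R² ≥ 0.8 wins. When no candidate passes, the configured
   fallback (default 9) is used with a prominent warning — reproducibility
   over silent failure.
4. **Modules.** Average-linkage hierarchical clustering of 1 − TOM, a tree
   cut into modules (below), module eigengenes as the first right-singular
   vector of the per-gene standardized module submatrix, iterative merging of
   modules whose eigengene dissimilarity 1 − cor(ME) clusters below 0.25, and
   membership kME = cor(gene, eigengene).
5. **Enrichment.** Every module × gene-set pair is tested with the one-sided
   (greater) Fisher exact test over the analyzed gene universe; −log10(p)
   fills the heatmap matrix; BH-adjusted q-values are reported alongside raw
   p, with raw p driving module selection by default.
6. **Prioritization.** Within each phenotype's enriched modules, region genes
   with own-module kME strictly above 0.7 are ranked by intramodular degree
   percentage — the share of possible within-module partners connected above
   an edge-weight threshold — and annotated with pLI (`top_tier`: pLI > 0.9).

# Tunable parameters

| parameter | default | units / range | rationale |
|---|---|---|---|
| `rpkm_threshold` | 0.3 | mean RPKM | stated filter of the workflow |
| `mode` | `unsigned_abs` | — | the printed similarity definition; `signed_shift` = (1+cor)/2 available |
| `candidates` | 1..20 | integer powers | standard scan range |
| `target_r2` | 0.8 | (0,1) | common scale-free fit criterion; the source analysis does not state its cutoff |
| `fallback_beta` | 9 | integer | the reference analysis' chosen power |
| `linkage` | average | — | UPGMA, the field convention for TOM trees |
| `cut_method` | `dynamic_branch` | — | branch-sensitive cutting; `static` available |
| `min_module_size` | 30 | genes | common default; the source says only "manually set … large sizes" |
| `gap_frac` | 0.005 | fraction | branch-gap acceptance, see below |
| `merge_cut_height` | 0.25 | eigengene dissimilarity | the merge height is the operative parameter (see *Design decisions*) |
| `alpha` | 0.05 | p | enrichment selection level |
| `kme_threshold` | 0.7 | correlation, strict > | stated membership cutoff |
| edge threshold | 90th percentile per module | weight quantile | no absolute cutoff is stated; a quantile is scale-free across β |

Every default standing in for a parameter the original analysis leaves
unstated is tagged `paper_unstated_default` in the run log, so a reader of
any run can see which knobs are reconstructions.

# The tree cut

The static cut takes connected components below a height and greys clusters
under the minimum size. The default `dynamic_branch` cut descends from the
root and accepts a branch as a module when it has at least
`min_module_size` leaves and its merge-height gap — the height at which it
joins the rest of the tree minus its own top merge height — exceeds
`gap_frac` times the branch's *internal height spread* (top minus lowest
merge height inside the branch; a branch with zero spread is accepted on any
positive gap). Descent stops at the first accepted branch; everything else is
grey.

The gap is measured relative to the branch's own spread rather than the total
tree height deliberately. On TOM dissimilarity trees almost all merge heights
compress into a narrow band near 1: on the reference benchmark the five
planted modules join the rest of the tree with absolute gaps of only
0.004–0.04 (tree height ≈ 1), while incidental joins among background genes
have gaps around 1e−4. Relative to each branch's internal spread those
numbers become ≥ 0.014 for true modules versus ~1e−4 for background joins —
two orders of magnitude of separation, against a factor of about two on the
absolute scale. The default `gap_frac = 0.005` sits in the middle of that
relative gap. Because descent stops at the first accepted branch, a module
with internal sub-structure comes out whole; when a weakly attached module is
instead over-split, the eigengene-merging stage (sub-modules driven by the
same latent factor have highly correlated eigengenes) fuses it back.

# Numerical choices

- **Similarity** is clamped to \[0, 1\] after the |cor| or (1+cor)/2 map to
  absorb floating-point excursions; zero-variance genes are a hard error
  naming the gene, since upstream filtering should have removed them.
- **Eigengene sign** is aligned so cor(ME, mean standardized module profile)
  ≥ 0; when that profile is constant (exactly opposed genes) the first gene
  is the reference. Because the SVD acts on X^T X = Σ x_g x_gᵀ, flipping the
  sign of any single gene leaves eigengenes unchanged up to this alignment.
- **Merging** iterates until a fixpoint; the module count never increases, so
  at most (initial module count) iterations occur.
- **Static cut** uses its own union-find over merge rows at or below the cut
  height, tolerating the tied or locally non-monotone heights average linkage
  can produce (where `stats::cutree` refuses).
- **Scale-free fit** returns R² = 0 with a `degenerate` flag when all
  connectivities are equal or fewer than two non-empty bins remain, rather
  than an error: a degenerate candidate is simply not selectable.
- **Fisher p** is the exact hypergeometric upper tail (`phyper`); the test
  suite checks it against an independent closed-form enumeration of the
  support to 1e−12, and the matrix TOM/similarity/degree code against naive
  scalar loops at the same tolerance.
- **Determinism.** All randomness flows from a single integer seed; the run
  log carries no timestamps, and the manifest md5-checksums every artifact,
  so identical configurations produce byte-identical runs.

# The synthetic generator

`synthetic_spec()` defaults define the package's reference benchmark: five
planted modules of 60 genes with loadings λ uniform in \[0.6, 0.9\], 100
background genes, 20 near-zero genes (exponential, mean 0.05 RPKM, removed by
the 0.3-RPKM filter), 120 samples. Each module has one latent per-sample
factor e_m ~ N(0,1); a module gene is
x_g = λ_g e_m + √(1 − λ_g²) ε_g on the log2 scale, so cor(x_g, e_m) = λ_g in
expectation, and RPKM = 2^(x + 3) − 1 (clipped at 0) so the pipeline's
log2(RPKM + 1) approximately recovers x. The offset 3 puts typical genes
around 8 RPKM, comfortably above the filter; clipping slightly distorts the
extreme low tail, which is accepted because the filter needs genuinely
low-RPKM genes. Phenotype sets are planted as seeded random halves (40% for
language impairment) of modules 1–4 plus 10–30 labeled background genes;
hypotonia is deliberately planted on background only, so a correct pipeline
reports no enriched module and an empty candidate section for it; the region
set covers 30% of module 1 plus background; and one hub gene (loading 0.95,
first gene of module 1) carries both the ASD and region labels, so it should
top the ASD candidate ranking. Draws occur in a fixed documented order
(per module: factor, loadings, noise; then background; then near-zero genes);
set planting reseeds at seed + 1 so the annotation is reproducible
independently of the expression stream.

What the generator does **not** emulate: BrainSpan's age/region sample
structure (metadata are flat), count noise and library-size effects (values
are generated directly on the log scale), correlated module factors (a knob
exists but defaults off), and gene-length effects in RPKM. Passing the
benchmark therefore demonstrates the pipeline's statistical machinery —
module recovery, enrichment calibration, ranking — not robustness to the
technical artifacts of real transcriptomes.

# Null calibration and exact-test conservativeness

Shuffling module labels and counting raw p < 0.05 across all module × set
pairs estimates the per-pair type-I rate. At the benchmark's margins
(universe 400, modules of 60, set sizes 29–50) the one-sided Fisher test is
conservative: summing the hypergeometric mass over each pair's rejection
region gives exact attained levels of 0.018–0.023, and the empirical 200-rep
rate converges there (≈ 0.021), not to the nominal 0.05. This is a known
property of discrete exact tests, not an implementation artifact — the
enrichment p-values are valid but conservative, which is the safe direction
for declaring modules enriched. The acceptance suite keeps a check of this
rate against the nominal band and documents the expected shortfall.

# Design decisions

- **Unsigned similarity by default.** The reference workflow's prose says
  "signed" while its printed definition is |cor|; the printed equation wins,
  and `signed_shift` is one configuration flag away. With unsigned
  similarity, anti-correlated genes land in the same module.
- **Merge rule.** "ME > 0.8" (dissimilarity 0.2) and "height 0.25" disagree;
  the height is taken as the operative parameter because eigengene merging is
  procedurally a tree cut at a height, and it is configurable.
- **Universe for enrichment** is the analyzed matrix's genes (conditioning on
  the genes that could have been in modules); "all annotated genes" is
  selectable.
- **Raw p drives selection** (mirroring the reference heatmap of raw
  −log10 p); BH q is computed and reported for every pair and can drive
  selection instead.
- **TOM as the degree/export weight** (configurable to adjacency): it is the
  last network transform before clustering, so hub ranking and module
  membership read off the same object.
- **The degree denominator** is module size − 1, so the statistic is "% of
  possible intramodular partners"; this reading of a hub-degree percentage is
  an assumption and is documented as such.
- **Genes in phenotype lists missing from the matrix** stay in the annotation
  (reported as not expressed) rather than being dropped, preserving the
  attrition trail; symbol matching is exact after upper-casing, with an
  optional user alias file and no built-in synonym resolution.

# Problem sizes and limitations

The test suite runs the reference benchmark (420 simulated genes, 120
samples, a few seconds per full pipeline run), 100 random oracle instances at
n ≤ 15, 500 random exact-test tables, and 200 label-shuffle replicates —
sizes chosen so the whole suite completes in well under a minute while the
oracle comparisons stay exhaustive.

Known limitations: dense matrices only (a `max_genes = 20000` guard refuses
larger inputs rather than thrashing); no block-wise network construction,
biweight midcorrelation or Spearman adjacency; no reimplementation of the
published Dynamic Hybrid tree cut with its PAM stage (the branch-gap cut plus
eigengene merging covers the same role); functional-term annotation (DAVID)
and pLI retrieval are out of scope — the pipeline exports per-module gene
lists and consumes pLI from a file. Exact reproduction of the reference
study's module count and candidate table would require the BrainSpan download
plus parameters (cut method, minimum module size, hub edge threshold) that
its description does not state.
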