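# coexmod

Weighted gene co-expression modules and candidate-gene prioritization for
region-phenotype association studies.

## The problem

Contiguous-gene deletion syndromes (the motivating case is the 22q13 region
deleted in Phelan–McDermid syndrome) present with several neurological
phenotypes — autism spectrum disorder, intellectual disability, seizures,
hypotonia, language impairment — but for most genes in the deleted interval
the phenotype contribution is unknown. `coexmod` implements a
guilt-by-association strategy on brain developmental transcriptomes
(BrainSpan-style RPKM matrices): build a weighted gene co-expression network
over the union of known phenotype genes and region genes, find co-expression
modules, test which modules are over-represented for each phenotype gene set
and for the region gene set, and rank region genes inside those modules as
candidate phenotype genes.

## The model

For log-transformed expression profiles $x_i$, the network is built from the
Pearson similarity

$$s_{ij} = \lvert \mathrm{cor}(x_i, x_j) \rvert$$

raised element-wise to a soft threshold, $a_{ij} = s_{ij}^{\beta}$, with
$\beta$ chosen as the smallest integer whose connectivity distribution
$k_i = \sum_{j \ne i} a_{ij}$ gives an approximate scale-free (power-law) fit
$R^2$ above a target. Adjacency is transformed to the topological overlap
matrix

$$\mathrm{TOM}_{ij} = \frac{\ell_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},
\qquad \ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj},$$

and genes are clustered on $1 - \mathrm{TOM}$ with average linkage. Modules
are branches of the dendrogram (minimum size 30 by default); each module is
summarized by its eigengene (first principal component of the standardized
module expression) and modules with eigengene dissimilarity below 0.25 are
merged. Module membership is $k_{ME}(g, m) = \mathrm{cor}(x_g, \mathrm{ME}_m)$.
Module × gene-set over-representation uses the one-sided Fisher exact test
over the analyzed gene universe, reported as $-\log_{10}(p)$ with BH-adjusted
q-values alongside. Candidates are region genes in phenotype-enriched modules
with own-module $k_{ME} > 0.7$, ranked by intramodular degree (the percent of
within-module partners connected above an edge-weight threshold), and
annotated with gnomAD pLI (`top_tier` = pLI > 0.9).

A factor-model synthetic-data generator (planted modules
$x_g = \lambda_g e_m + \sqrt{1 - \lambda_g^2}\,\varepsilon_g$ mapped to RPKM,
planted gene-set enrichment, near-zero genes for the expression filter) makes
every stage testable without the external download.

## Worked example

```r
library(coexmod)

spec <- synthetic_spec()                      # reference benchmark
sim  <- simulate_expression(spec)
annotation <- plant_gene_sets(sim$truth, spec)

expr <- filter_low_expression(log_transform(drop_zero_genes(sim$expression)))
fit  <- fit_coexpression(expr)                # network + modules in one call
summary(fit)
```

```
Weighted co-expression fit (beta = 7, 100 grey genes)
soft threshold: R2 = 0.862 at beta = 7
    module size var_explained mean_kme
      blue   60         0.543    0.731
     brown   60         0.547    0.734
     green   60         0.574    0.753
 turquoise   60         0.649    0.802
    yellow   60         0.610    0.775
```

The scan selected the soft threshold `beta = 7` (smallest power with
scale-free fit R² ≥ 0.8 on this matrix); all five planted modules of 60 genes
are recovered exactly and the 100 background genes stay grey. Enrichment
recovers the planted module–phenotype pairings:

```r
enr <- fisher_enrichment(fit$partition, annotation)
head(enr[order(enr$p), c("module", "set", "a", "b", "p", "q")], 5)
```

```
      module                 set  a  b            p            q
4  turquoise                 ASD 30 30 7.316146e-16 7.316146e-15
6       blue                  ID 30 30 7.316146e-16 7.316146e-15
12     brown            seizures 30 30 7.316146e-16 7.316146e-15
20    yellow language_impairment 24 36 7.944906e-15 5.958680e-14
29 turquoise        region_22q13 19 41 9.409831e-11 5.645899e-10
```

Each planted (module, set) pair attains the smallest p in its set's column —
e.g. 30 of the turquoise module's 60 genes carry the ASD label against a
400-gene universe. `score_recovery(sim$truth, fit$partition)$ari` returns
`1`, perfect agreement with the planted partition. The whole pipeline —
including intramodular degrees, Cytoscape-ready edge lists, the candidate
table and a checksummed manifest — runs as

```r
art <- run_pipeline(list(simulate = TRUE, paths = list(out_dir = "run1")))
```

or from a shell via the thin wrapper `inst/scripts/coexmod.R`
(`simulate`, `run`, `validate` subcommands).

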