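# Synthetic expression with planted co-expression modules and planted gene-set
# enrichment. A log-scale factor model: each planted module has one latent
# per-sample eigengene e_m ~ N(0,1); a module gene g has
#   x_g = lambda_g * e_m + sqrt(1 - lambda_g^2) * eps_g,   eps_g ~ N(0,1)
# so cor(x_g, e_m) = lambda_g in expectation. Background genes are pure noise.
# Log values map to RPKM via v = 2^(x + offset) - 1 (clipped at 0) so the
# pipeline's log2(RPKM + 1) approximately recovers x; near-zero genes are
# drawn exponentially with mean 0.05 RPKM to exercise the 0.3-RPKM filter.
#
# Randomness uses R's default Mersenne-Twister stream seeded once; draws occur
# in a fixed documented order (per module: factor, loadings, noise; then
# background; then near-zero genes; set planting reseeds at seed + 1).

#' Specification of a synthetic co-expression dataset
#'
#' The defaults are the package's reference benchmark: 5 modules of 60 genes
#' with loadings uniform in \[0.6, 0.9\], 100 background genes, 20 near-zero
#' genes, 120 samples, a high-loading hub gene (loading 0.95) in module 1
#' carrying ASD and region labels, phenotype sets planted in modules 1-4 plus
#' background labels, hypotonia deliberately planted nowhere (background
#' labels only) to exercise the no-enriched-module path, and the region set
#' planted in module 1.
#'
#' @param n_samples Number of samples.
#' @param modules List of `list(size, loading = c(lo, hi))` per planted module.
#' @param n_background Pure-noise genes.
#' @param n_near_zero Genes with mean 0.05 RPKM (removed by the 0.3 filter).
#' @param hub `list(module, loading, sets)` for the planted hub gene (first
#'   gene of the module), or NULL.
#' @param set_plants List of `list(set, module, fraction, n_background)`;
#'   `module = NA` plants background labels only.
#' @param region_plants Same shape for the region set.
#' @param rpkm_offset Location constant added on the log2 scale before the
#'   RPKM back-map, default 3.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(
    n_samples = 120L,
    modules = rep(list(list(size = 60L, loading = c(0.6, 0.9))), 5L),
    n_background = 100L,
    n_near_zero = 20L,
    hub = list(module = 1L, loading = 0.95,
               sets = c("ASD", "region_22q13")),
    set_plants = list(
      list(set = "ASD",                 module = 1L, fraction = 0.5, n_background = 20L),
      list(set = "ID",                  module = 2L, fraction = 0.5, n_background = 20L),
      list(set = "seizures",            module = 3L, fraction = 0.5, n_background = 20L),
      list(set = "language_impairment", module = 4L, fraction = 0.4, n_background = 10L),
      list(set = "hypotonia",           module = NA, fraction = 0,   n_background = 30L)),
    region_plants = list(
      list(set = "region_22q13", module = 1L, fraction = 0.3, n_background = 10L)),
    rpkm_offset = 3,
    seed = 20231026L) {
  for (m in modules) {
    stopifnot(m$size >= 2L, all(m$loading > 0), all(m$loading <= 1))
  }
  for (p in c(set_plants, region_plants))
    stopifnot(p$fraction >= 0, p$fraction <= 1)
  structure(list(n_samples = as.integer(n_samples), modules = modules,
                 n_background = as.integer(n_background),
                 n_near_zero = as.integer(n_near_zero), hub = hub,
                 set_plants = set_plants, region_plants = region_plants,
                 rpkm_offset = rpkm_offset, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Simulate an expression matrix with planted modules
#'
#' @param spec A `synthetic_spec`.
#' @return List with `expression` (an `expr_matrix` in RPKM units, with flat
#'   age/structure sample metadata) and `truth` (a `planted_truth`: named
#'   `module` vector with NA for background and near-zero genes, the latent
#'   `factors` matrix (modules x samples), the per-gene `loadings`, the
#'   `hub_gene` name, and the spec).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  ns <- spec$n_samples
  n_mod <- length(spec$modules)
  samples <- sprintf("S%03d", seq_len(ns))
  factors <- matrix(NA_real_, n_mod, ns,
                    dimnames = list(sprintf("m%d", seq_len(n_mod)), samples))
  xs <- list(); loadings <- c(); truth_mod <- c()
  for (m in seq_len(n_mod)) {
    sz <- spec$modules[[m]]$size
    lr <- spec$modules[[m]]$loading
    e <- stats::rnorm(ns)
    factors[m, ] <- e
    lam <- stats::runif(sz, lr[1L], lr[2L])
    if (!is.null(spec$hub) && identical(as.integer(spec$hub$module), m))
      lam[1L] <- spec$hub$loading
    eps <- matrix(stats::rnorm(sz * ns), sz, ns)
    X <- lam %o% e + sqrt(1 - lam^2) * eps
    rownames(X) <- sprintf("M%dG%03d", m, seq_len(sz))
    xs[[m]] <- X
    loadings <- c(loadings, stats::setNames(lam, rownames(X)))
    truth_mod <- c(truth_mod, stats::setNames(rep(m, sz), rownames(X)))
  }
  X <- do.call(rbind, xs)
  if (spec$n_background > 0) {
    B <- matrix(stats::rnorm(spec$n_background * ns), spec$n_background, ns)
    rownames(B) <- sprintf("B%03d", seq_len(spec$n_background))
    X <- rbind(X, B)
    truth_mod <- c(truth_mod,
                   stats::setNames(rep(NA_integer_, spec$n_background),
                                   rownames(B)))
  }
  rpkm <- pmax(2^(X + spec$rpkm_offset) - 1, 0)
  if (spec$n_near_zero > 0) {
    Z <- matrix(stats::rexp(spec$n_near_zero * ns, rate = 1 / 0.05),
                spec$n_near_zero, ns)
    rownames(Z) <- sprintf("Z%03d", seq_len(spec$n_near_zero))
    rpkm <- rbind(rpkm, Z)
    truth_mod <- c(truth_mod,
                   stats::setNames(rep(NA_integer_, spec$n_near_zero),
                                   rownames(Z)))
  }
  colnames(rpkm) <- samples
  meta <- data.frame(sample = samples, age = "synthetic",
                     structure_name = "synthetic",
                     stringsAsFactors = FALSE)
  hub_gene <- if (is.null(spec$hub)) NULL else
    sprintf("M%dG%03d", as.integer(spec$hub$module), 1L)
  truth <- structure(list(module = truth_mod, factors = factors,
                          loadings = loadings, hub_gene = hub_gene,
                          spec = spec),
                     class = "planted_truth")
  list(expression = expr_matrix(rpkm, "RPKM", sample_meta = meta),
       truth = truth)
}

#' Plant gene-set labels over a simulated dataset
#'
#' For every plant, a seeded random subset of the target module of the stated
#' fraction gets the label, plus the stated number of random background genes.
#' The hub gene is always included in its declared sets. Sub-sampling reseeds
#' at `spec$seed + 1` so the annotation is reproducible independently of when
#' the expression stream was consumed.
#'
#' @param truth A `planted_truth` from [simulate_expression()].
#' @param spec The same `synthetic_spec`.
#' @return A `gene_annotation` table.
#' @export
plant_gene_sets <- function(truth, spec) {
  set.seed(spec$seed + 1L)
  bg <- names(truth$module)[is.na(truth$module) &
                              startsWith(names(truth$module), "B")]
  sets <- list()
  for (p in c(spec$set_plants, spec$region_plants)) {
    genes <- character(0)
    if (!is.na(p$module)) {
      mod_genes <- names(truth$module)[!is.na(truth$module) &
                                         truth$module == p$module]
      n_lab <- round(p$fraction * length(mod_genes))
      if (p$fraction > 0 && n_lab < 1)
        warnf("plant for %s labels zero genes (fraction %g of %d)",
              p$set, p$fraction, length(mod_genes))
      if (n_lab >= 1) genes <- sample(mod_genes, n_lab)
    }
    if (p$n_background > 0 && length(bg))
      genes <- c(genes, sample(bg, min(p$n_background, length(bg))))
    if (!is.null(spec$hub) && !is.null(truth$hub_gene) &&
        p$set %in% spec$hub$sets)
      genes <- union(genes, truth$hub_gene)
    if (length(genes))
      sets[[length(sets) + 1L]] <- gene_set(p$set, genes)
  }
  build_annotation(sets)
}

#' Score module recovery against the planted truth
#'
#' Adjusted Rand index over genes carrying a true module label (background
#' excluded; grey counts as its own recovered class), plus the best-match
#' Jaccard of every true module.
#'
#' @param truth A `planted_truth`.
#' @param partition A `module_partition` on (a superset or subset of) the same
#'   genes.
#' @return List with `ari` and `jaccard` (named per true module).
#' @export
score_recovery <- function(truth, partition) {
  planted <- names(truth$module)[!is.na(truth$module)]
  planted <- intersect(planted, names(partition$colors))
  if (!length(planted)) stopf("no planted gene present in the partition")
  true_lab <- truth$module[planted]
  rec_lab <- partition$colors[planted]
  ari <- mclust::adjustedRandIndex(true_lab, rec_lab)
  jac <- stats::setNames(numeric(0), character(0))
  for (m in sort(unique(true_lab))) {
    tg <- planted[true_lab == m]
    best <- 0
    for (cl in setdiff(unique(rec_lab), "grey")) {
      rg <- planted[rec_lab == cl]
      j <- length(intersect(tg, rg)) / length(union(tg, rg))
      best <- max(best, j)
    }
    jac[sprintf("m%d", m)] <- best
  }
  list(ari = ari, jaccard = jac)
}
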