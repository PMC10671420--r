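# Module x gene-set over-representation: one-sided Fisher's exact test
# (hypergeometric upper tail) per (module, set) pair over the analyzed gene
# universe, BH adjustment across all pairs, and the -log10(p) heatmap matrix.

#' One-sided Fisher's exact test for a 2x2 enrichment table
#'
#' Counts: `a` = genes in the module and the set, `b` = in the module only,
#' `c` = in the set only, `d` = in neither. The one-sided (greater) p-value is
#' the hypergeometric upper tail P(X >= a) with `a + c` successes in an urn of
#' `a + b + c + d`, drawing `a + b`.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return List with `p` (one-sided p-value) and `odds_ratio`
#'   (sample odds ratio `ad / bc`, `Inf` when `bc == 0` and `ad > 0`).
#' @export
fisher_one_sided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  p <- stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  list(p = min(p, 1), odds_ratio = or)
}

#' Module x gene-set enrichment table
#'
#' Tests every (module, set) pair for over-representation. The universe
#' defaults to the genes of the analyzed expression matrix (i.e. the genes
#' carried by the partition); grey genes are excluded from modules but remain
#' in the universe. Benjamini-Hochberg adjustment is applied across all
#' reported pairs alongside the raw p.
#'
#' @param partition A `module_partition`.
#' @param annotation A `gene_annotation` table.
#' @param universe Character vector of gene symbols; default = all genes in
#'   the partition.
#' @param log Optional run log.
#' @return data.frame of class `enrichment_result` with columns module, set,
#'   a, b, c, d, odds_ratio, p, q, neglog10_p.
#' @export
fisher_enrichment <- function(partition, annotation, universe = NULL,
                              log = NULL) {
  stopifnot(inherits(partition, "module_partition"),
            inherits(annotation, "gene_annotation"))
  if (is.null(universe)) universe <- names(partition$colors)
  universe <- unique(universe)
  N <- length(universe)
  sets <- annotation_sets(annotation)
  mods <- module_colors(partition)
  if (!length(mods)) stopf("partition has no modules to test")
  rows <- list()
  for (s in sets) {
    set_genes <- intersect(annotation_genes(annotation, s), universe)
    if (length(set_genes) == 0L) {
      warnf("set '%s' has no genes in the universe; skipped", s)
      log_event(log, "enrichment", "set_skipped", s)
      next
    }
    for (m in mods) {
      mod_genes <- intersect(
        names(partition$colors)[partition$colors == m], universe)
      a <- length(intersect(mod_genes, set_genes))
      b <- length(mod_genes) - a
      c_ <- length(set_genes) - a
      d <- N - a - b - c_
      ft <- fisher_one_sided(a, b, c_, d)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, set = s, a = a, b = b, c = c_, d = d,
        odds_ratio = ft$odds_ratio, p = ft$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$neglog10_p <- -log10(out$p)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Module-by-set matrix of -log10(p)
#'
#' @param result An `enrichment_result`.
#' @return Numeric matrix, module colors as rows, set names as columns.
#' @export
heatmap_matrix <- function(result) {
  mods <- unique(result$module)
  sets <- unique(result$set)
  M <- matrix(0, length(mods), length(sets), dimnames = list(mods, sets))
  for (i in seq_len(nrow(result)))
    M[result$module[i], result$set[i]] <- result$neglog10_p[i]
  M
}

#' Modules enriched per gene set
#'
#' @param result An `enrichment_result`.
#' @param alpha Significance level, default 0.05.
#' @param use_adjusted Use BH-adjusted q instead of raw p, default FALSE
#'   (raw p mirrors the original analysis; q is reported side by side).
#' @return Named list: per set, the module colors with (q or p) < alpha,
#'   sorted by ascending p.
#' @export
enriched_modules <- function(result, alpha = 0.05, use_adjusted = FALSE) {
  crit <- if (use_adjusted) result$q else result$p
  out <- list()
  for (s in unique(result$set)) {
    sel <- result$set == s & crit < alpha
    sub <- result[sel, , drop = FALSE]
    out[[s]] <- sub$module[order(sub$p)]
  }
  out
}
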