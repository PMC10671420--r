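# The central fit: expression -> similarity -> soft threshold -> adjacency ->
# TOM -> dendrogram -> modules -> eigengenes -> merge -> kME, bundled into one
# classed object.

#' Fit a weighted co-expression network and its module decomposition
#'
#' Runs the full network-and-modules stage on a log-transformed expression
#' matrix: pairwise Pearson similarity, soft-threshold selection by scale-free
#' topology fit, element-wise power adjacency, topological overlap, average-
#' linkage clustering of the TOM dissimilarity, tree cut into modules,
#' module eigengenes, eigengene-based merging, and kME membership.
#'
#' @param M An `expr_matrix` in LOG2_RPKM_PLUS1 units (or a plain numeric
#'   genes x samples matrix on a log scale).
#' @param mode Similarity mode, `"unsigned_abs"` (default) or `"signed_shift"`.
#' @param candidates Candidate soft-threshold powers, default 1:20.
#' @param target_r2 Scale-free fit target, default 0.8.
#' @param fallback_beta Power used when no candidate reaches the target,
#'   default 9.
#' @param beta Fix the power directly and skip the scan (NULL = scan).
#' @param linkage Clustering linkage, default `"average"`.
#' @param cut_method `"dynamic_branch"` (default) or `"static"`.
#' @param cut_height Height for the static cut.
#' @param min_module_size Minimum module size, default 30.
#' @param gap_frac Branch-gap fraction for the dynamic cut, default 0.005.
#' @param merge_cut_height Eigengene-dissimilarity merge cut, default 0.25.
#' @param max_genes Guard against accidental huge dense allocations,
#'   default 20000.
#' @param log Optional run log.
#' @return An object of class `coex_fit` with components `soft`
#'   (soft-threshold report), `beta`, `similarity`, `adjacency`, `tom`,
#'   `dendrogram`, `partition`, `eigengenes`, `kme`, `expression`.
#' @export
fit_coexpression <- function(M, mode = "unsigned_abs", candidates = 1:20,
                             target_r2 = 0.8, fallback_beta = 9L, beta = NULL,
                             linkage = "average",
                             cut_method = "dynamic_branch", cut_height = NULL,
                             min_module_size = 30L, gap_frac = 0.005,
                             merge_cut_height = 0.25, max_genes = 20000L,
                             log = NULL) {
  v <- if (inherits(M, "expr_matrix")) M$values else M
  if (nrow(v) > max_genes)
    stopf("%d genes exceeds max_genes = %d; dense matrices would be too large",
          nrow(v), max_genes)
  S <- similarity(v, mode)
  if (is.null(beta)) {
    soft <- pick_soft_threshold(S, candidates, target_r2, fallback_beta,
                                log = log)
    beta <- soft$chosen_beta
  } else {
    soft <- NULL
  }
  A <- adjacency(S, beta)
  TOM <- topological_overlap(A)
  D <- tom_dissimilarity(TOM)
  dendro <- hierarchical_cluster(D, linkage)
  partition <- cut_modules(dendro, cut_method, cut_height, min_module_size,
                           gap_frac)
  log_event(log, "modules", "initial_cut",
            sprintf("modules=%d grey=%d method=%s min_size=%d",
                    length(partition$module_sizes),
                    sum(partition$colors == "grey"), cut_method,
                    min_module_size))
  if (length(partition$module_sizes) == 0L)
    stopf("no module of size >= %d found", min_module_size)
  ME <- module_eigengenes(v, partition)
  merged <- merge_close_modules(v, partition, ME, merge_cut_height, log = log)
  partition <- merged$partition
  ME <- merged$ME
  kme <- module_membership(v, ME)
  structure(list(soft = soft, beta = as.integer(beta), similarity = S,
                 adjacency = A, tom = TOM, dendrogram = dendro,
                 partition = partition, eigengenes = ME, kme = kme,
                 expression = M, mode = mode,
                 params = list(linkage = linkage, cut_method = cut_method,
                               cut_height = cut_height,
                               min_module_size = min_module_size,
                               gap_frac = gap_frac,
                               merge_cut_height = merge_cut_height)),
            class = "coex_fit")
}

#' @export
print.coex_fit <- function(x, ...) {
  cat(sprintf("coex_fit: %d genes, %d samples | mode = %s, beta = %d%s\n",
              nrow(x$similarity), ncol(x$eigengenes$ME), x$mode, x$beta,
              if (!is.null(x$soft) && x$soft$fallback_used) " (fallback)" else ""))
  print(x$partition)
  invisible(x)
}

#' @export
summary.coex_fit <- function(object, ...) {
  sz <- sort(object$partition$module_sizes, decreasing = TRUE)
  ve <- object$eigengenes$var_explained[names(sz)]
  own <- own_module_kme(object$kme, object$partition)
  mean_kme <- vapply(names(sz), function(cl) {
    mean(own[names(object$partition$colors)[object$partition$colors == cl]])
  }, numeric(1))
  out <- list(beta = object$beta, soft = object$soft,
              n_grey = sum(object$partition$colors == "grey"),
              modules = data.frame(module = names(sz), size = as.integer(sz),
                                   var_explained = unname(ve),
                                   mean_kme = unname(mean_kme),
                                   stringsAsFactors = FALSE))
  class(out) <- "summary.coex_fit"
  out
}

#' @export
print.summary.coex_fit <- function(x, ...) {
  cat(sprintf("Weighted co-expression fit (beta = %d, %d grey genes)\n",
              x$beta, x$n_grey))
  if (!is.null(x$soft))
    cat(sprintf("soft threshold: R2 = %.3f at beta = %d%s\n",
                x$soft$table$r2[x$soft$table$beta == x$beta][1],
                x$beta, if (x$soft$fallback_used) " [fallback]" else ""))
  print(x$modules, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot a co-expression fit
#'
#' `type = "dendrogram"`: gene dendrogram with a module color bar.
#' `type = "soft"`: signed scale-free R-squared against the candidate powers.
#' `type = "heatmap"`: image of the TOM (genes ordered by the dendrogram).
#'
#' @param x A `coex_fit`.
#' @param type One of `"dendrogram"`, `"soft"`, `"heatmap"`.
#' @param ... Passed to the underlying plot call.
#' @export
plot.coex_fit <- function(x, type = c("dendrogram", "soft", "heatmap"), ...) {
  type <- match.arg(type)
  if (type == "soft") {
    if (is.null(x$soft)) stopf("fit was run with a fixed beta; no scan to plot")
    tab <- x$soft$table
    graphics::plot(tab$beta, tab$r2, type = "b", xlab = "soft threshold (beta)",
                   ylab = "signed scale-free fit R2", ...)
    graphics::abline(h = x$soft$target_r2, lty = 2)
    graphics::abline(v = x$beta, col = "red", lty = 3)
  } else if (type == "dendrogram") {
    op <- graphics::par(mfrow = c(2, 1), mar = c(0.5, 4, 2, 1))
    on.exit(graphics::par(op))
    graphics::plot(x$dendrogram, labels = FALSE, hang = -1,
                   main = "TOM dissimilarity clustering", xlab = "", sub = "", ...)
    cols <- x$partition$colors[x$dendrogram$labels[x$dendrogram$order]]
    cols[!cols %in% grDevices::colors()] <- "grey40"
    graphics::par(mar = c(2, 4, 0.5, 1))
    graphics::image(matrix(seq_along(cols)), col = cols, axes = FALSE,
                    ylab = "module")
  } else {
    ord <- x$dendrogram$order
    graphics::image(x$tom[ord, ord],
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    axes = FALSE, main = "topological overlap", ...)
  }
  invisible(x)
}
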