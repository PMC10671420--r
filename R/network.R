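# Network construction: pairwise Pearson similarity, soft-threshold selection
# by scale-free topology fit, element-wise power adjacency, and the topological
# overlap matrix (TOM) with its dissimilarity.
#
# The similarity is s_ij = |cor(x_i, x_j)| in the default unsigned mode, or
# (1 + cor)/2 in signed mode. Adjacency is a_ij = s_ij^beta. The unsigned TOM
# (Zhang-Horvath form) is
#   t_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij),  l_ij = sum_u a_iu a_uj
# with the diagonal excluded from k and l and set to 1 in the result.

#' Pairwise co-expression similarity
#'
#' Pearson correlation between gene expression profiles, mapped into \[0, 1\]:
#' `unsigned_abs` takes the absolute value, `signed_shift` takes
#' `(1 + cor) / 2`.
#'
#' @param M An `expr_matrix` in LOG2_RPKM_PLUS1 units, or a plain numeric
#'   genes x samples matrix.
#' @param mode `"unsigned_abs"` (default) or `"signed_shift"`.
#' @return A symmetric genes x genes matrix with unit diagonal, entries in
#'   \[0, 1\], with attribute `mode`.
#' @export
similarity <- function(M, mode = c("unsigned_abs", "signed_shift")) {
  mode <- match.arg(mode)
  v <- if (inherits(M, "expr_matrix")) {
    if (M$unit_state != "LOG2_RPKM_PLUS1")
      stopf("similarity expects log-transformed expression")
    M$values
  } else M
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance gene(s): %s",
          paste(utils::head(rownames(v)[sds == 0], 5L), collapse = ", "))
  cc <- stats::cor(t(v))
  S <- if (mode == "unsigned_abs") abs(cc) else (1 + cc) / 2
  S <- pmin(pmax(S, 0), 1)
  diag(S) <- 1
  attr(S, "mode") <- mode
  S
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivity vector into `n_bins` equal-width bins, regresses
#' log10(mean frequency per bin) on log10(bin center) over non-empty bins and
#' returns the R-squared signed by the negative of the slope sign, so positive
#' values indicate the decreasing tail of a power law.
#'
#' @param k Connectivity vector (row sums of adjacency with the diagonal
#'   excluded).
#' @param n_bins Number of equal-width bins, default 10.
#' @return List with `r2` (signed), `slope`, and `degenerate` (TRUE when all
#'   connectivities are identical or fewer than 2 non-empty bins remain).
#' @export
scale_free_fit <- function(k, n_bins = 10L) {
  stopifnot(is.numeric(k), length(k) >= 2L)
  if (max(k) - min(k) < .Machine$double.eps^0.5)
    return(list(r2 = 0, slope = NA_real_, degenerate = TRUE))
  brk <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- findInterval(k, brk, rightmost.closed = TRUE, all.inside = TRUE)
  freq <- tabulate(bin, nbins = n_bins) / length(k)
  centers <- (brk[-1L] + brk[-(n_bins + 1L)]) / 2
  ok <- freq > 0 & centers > 0
  if (sum(ok) < 2L)
    return(list(r2 = 0, slope = NA_real_, degenerate = TRUE))
  fit <- stats::lm.fit(cbind(1, log10(centers[ok])), log10(freq[ok]))
  slope <- fit$coefficients[2L]
  y <- log10(freq[ok])
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(r2 = unname(-sign(slope) * r2), slope = unname(slope),
       degenerate = FALSE)
}

#' Raise similarity to the soft-threshold power
#'
#' @param S Similarity matrix.
#' @param beta Positive integer power.
#' @return Adjacency matrix `S^beta` (element-wise) with attribute `beta`.
#' @export
adjacency <- function(S, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 1 || beta != round(beta))
    stopf("beta must be a positive integer (got %s)", format(beta))
  A <- S^beta
  diag(A) <- 1
  attr(A, "beta") <- as.integer(beta)
  attr(A, "mode") <- attr(S, "mode")
  A
}

#' Whole-network connectivity
#'
#' Row sums of adjacency with the diagonal excluded.
#'
#' @param A Adjacency matrix.
#' @return Numeric vector, one entry per gene.
#' @export
connectivity <- function(A) {
  rowSums(A) - diag(A)
}

#' Choose the soft threshold by scale-free topology fit
#'
#' For each candidate power the similarity matrix is raised element-wise, the
#' connectivity distribution is fit against a power law, and the smallest
#' candidate whose signed R-squared reaches `target_r2` is chosen. If none
#' does, the configured fallback is used and flagged.
#'
#' @param S Similarity matrix.
#' @param candidates Ascending positive integer powers, default 1:20.
#' @param target_r2 Fit threshold in (0, 1), default 0.8.
#' @param fallback_beta Power used when no candidate meets the target,
#'   default 9.
#' @param n_bins Bins for [scale_free_fit()].
#' @param log Optional run log.
#' @return List of class `soft_threshold_report`: `table` (data.frame with
#'   beta, signed r2, slope, mean/median connectivity, degenerate flag),
#'   `chosen_beta`, `target_r2`, `fallback_used`.
#' @export
pick_soft_threshold <- function(S, candidates = 1:20, target_r2 = 0.8,
                                fallback_beta = 9L, n_bins = 10L, log = NULL) {
  stopifnot(length(candidates) >= 1L, !is.unsorted(candidates),
            all(candidates >= 1), target_r2 > 0, target_r2 < 1)
  rows <- lapply(candidates, function(b) {
    k <- connectivity(adjacency(S, b))
    f <- scale_free_fit(k, n_bins)
    data.frame(beta = as.integer(b), r2 = f$r2, slope = f$slope,
               mean_k = mean(k), median_k = stats::median(k),
               degenerate = f$degenerate)
  })
  tab <- do.call(rbind, rows)
  hit <- which(!tab$degenerate & tab$r2 >= target_r2)
  fallback_used <- length(hit) == 0L
  chosen <- if (fallback_used) as.integer(fallback_beta) else tab$beta[hit[1L]]
  if (fallback_used) {
    warnf("no candidate power reached scale-free fit R2 >= %g; falling back to beta = %d",
          target_r2, chosen)
    log_event(log, "network", "soft_threshold_fallback",
              sprintf("beta=%d target_r2=%g", chosen, target_r2))
  } else {
    log_event(log, "network", "soft_threshold_chosen",
              sprintf("beta=%d r2=%.4f", chosen, tab$r2[hit[1L]]))
  }
  structure(list(table = tab, chosen_beta = chosen, target_r2 = target_r2,
                 fallback_used = fallback_used),
            class = "soft_threshold_report")
}

#' @export
print.soft_threshold_report <- function(x, ...) {
  cat(sprintf("soft-threshold report: chosen beta = %d%s (target R2 = %g)\n",
              x$chosen_beta, if (x$fallback_used) " [fallback]" else "",
              x$target_r2))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Topological overlap matrix
#'
#' Unsigned TOM of a weighted adjacency matrix; the dissimilarity `1 - TOM`
#' drives the module clustering.
#'
#' @param A Symmetric adjacency matrix with entries in \[0, 1\].
#' @return Symmetric matrix with unit diagonal and entries in \[0, 1\];
#'   attribute `beta` is carried over from `A`.
#' @export
topological_overlap <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  A0 <- A
  diag(A0) <- 0
  k <- rowSums(A0)
  L <- A0 %*% A0                      # l_ij = sum_{u != i,j} a_iu a_uj
  kmin <- outer(k, k, pmin)
  Tm <- (L + A0) / (kmin + 1 - A0)
  Tm[kmin + 1 - A0 == 0] <- 0
  diag(Tm) <- 1
  Tm <- pmin(pmax(Tm, 0), 1)
  dimnames(Tm) <- dimnames(A)
  attr(Tm, "beta") <- attr(A, "beta")
  Tm
}

#' TOM dissimilarity
#' @param TOM A topological overlap matrix.
#' @return `1 - TOM` with a zero diagonal.
#' @export
tom_dissimilarity <- function(TOM) {
  D <- 1 - TOM
  diag(D) <- 0
  D
}
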