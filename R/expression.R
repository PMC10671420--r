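# Expression preprocessing: ingest an RPKM genes x samples matrix, drop
# zero-sum genes, log2(RPKM + 1) transform, filter genes with mean RPKM below
# 0.3, subset to the annotated universe, and flag (never remove) sample
# outliers by hierarchical clustering of samples.

#' Construct an expression matrix object
#'
#' Thin container around a numeric genes x samples matrix carrying the unit
#' state (`RPKM` or `LOG2_RPKM_PLUS1`), the per-gene means on the RPKM scale
#' (needed by the low-expression filter after the log transform), and optional
#' per-sample metadata.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids). All values must be >= 0 and
#'   non-missing.
#' @param unit_state `"RPKM"` or `"LOG2_RPKM_PLUS1"`.
#' @param sample_meta Optional data.frame of per-sample attributes (e.g. age,
#'   brain structure), one row per sample.
#' @param rpkm_means Per-gene means on the RPKM scale; computed from `values`
#'   when the unit state is RPKM.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, unit_state = "RPKM", sample_meta = NULL,
                        rpkm_means = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  unit_state <- match.arg(unit_state, c("RPKM", "LOG2_RPKM_PLUS1"))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stopf("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stopf("duplicate sample ids")
  if (anyNA(values)) stopf("missing values are not supported (NA cell found)")
  if (any(values < 0)) stopf("negative expression value found")
  if (!is.null(sample_meta)) {
    stopifnot(is.data.frame(sample_meta))
    if (nrow(sample_meta) != ncol(values))
      stopf("sample_meta rows (%d) do not match samples (%d)",
            nrow(sample_meta), ncol(values))
  }
  if (is.null(rpkm_means)) {
    if (unit_state != "RPKM")
      stopf("rpkm_means must be supplied for a log-transformed matrix")
    rpkm_means <- rowMeans(values)
  }
  structure(list(values = values, unit_state = unit_state,
                 rpkm_means = rpkm_means, sample_meta = sample_meta),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit_state))
  invisible(x)
}

#' Gene / sample identifiers of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Load an expression matrix from disk
#'
#' Two dialects are supported. Plain: a TSV/CSV with gene symbols in the first
#' column and a header of sample ids. BrainSpan-style triple: an
#' `expression_matrix.csv` whose first column is a numeric row index, together
#' with a `rows_metadata.csv` providing a `gene_symbol` column and a
#' `columns_metadata.csv` providing per-sample attributes (e.g. `age`,
#' `structure_name`).
#'
#' Duplicate gene rows are collapsed by keeping the row with the highest mean
#' (logged).
#'
#' @param matrix_path Path to the expression matrix file.
#' @param row_meta_path,col_meta_path Optional BrainSpan-dialect metadata files.
#' @param sep Field separator; guessed from the extension when `NULL`
#'   (`.csv` is comma, anything else tab).
#' @param log Optional run log.
#' @return An `expr_matrix` in RPKM units.
#' @export
load_expression <- function(matrix_path, row_meta_path = NULL,
                            col_meta_path = NULL, sep = NULL, log = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", matrix_path)) "," else "\t"
  df <- utils::read.table(matrix_path, sep = sep, header = is.null(row_meta_path),
                          quote = "", comment.char = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(row_meta_path)) {
    rows <- utils::read.csv(row_meta_path, stringsAsFactors = FALSE)
    if (!"gene_symbol" %in% colnames(rows))
      stopf("rows metadata lacks a gene_symbol column")
    if (nrow(rows) != nrow(df))
      stopf("rows metadata (%d) does not match matrix rows (%d)",
            nrow(rows), nrow(df))
    genes <- toupper(rows$gene_symbol)
    vals <- as.matrix(df[, -1L, drop = FALSE])  # first column = row index
  } else {
    genes <- toupper(as.character(df[[1L]]))
    vals <- as.matrix(df[, -1L, drop = FALSE])
  }
  storage.mode(vals) <- "double"
  if (anyNA(vals)) stopf("missing values in expression matrix")
  if (any(vals < 0)) stopf("negative expression value in %s", matrix_path)
  sample_meta <- NULL
  if (!is.null(col_meta_path)) {
    sample_meta <- utils::read.csv(col_meta_path, stringsAsFactors = FALSE)
    if (nrow(sample_meta) != ncol(vals))
      stopf("columns metadata (%d) does not match matrix columns (%d)",
            nrow(sample_meta), ncol(vals))
  }
  if (is.null(colnames(vals)) || !any(nzchar(colnames(vals))))
    colnames(vals) <- sprintf("S%03d", seq_len(ncol(vals)))
  # collapse duplicate gene rows: keep highest-mean row
  if (anyDuplicated(genes)) {
    means <- rowMeans(vals)
    keep <- unlist(lapply(split(seq_along(genes), genes),
                          function(ix) ix[which.max(means[ix])]))
    n_drop <- length(genes) - length(keep)
    log_event(log, "preprocess", "duplicate_genes_collapsed",
              sprintf("n=%d", n_drop))
    keep <- sort(keep)
    vals <- vals[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  rownames(vals) <- genes
  expr_matrix(vals, "RPKM", sample_meta = sample_meta)
}

#' Remove genes with zero total expression
#'
#' Genes whose RPKM values sum to exactly zero across all samples carry no
#' signal and are removed before any transformation.
#'
#' @param M An `expr_matrix` in RPKM units.
#' @param log Optional run log.
#' @return Filtered `expr_matrix`.
#' @export
drop_zero_genes <- function(M, log = NULL) {
  stopifnot(inherits(M, "expr_matrix"))
  if (M$unit_state != "RPKM") stopf("drop_zero_genes expects RPKM units")
  keep <- rowSums(M$values) > 0
  if (!any(keep)) stopf("empty matrix: all genes sum to 0 RPKM")
  log_event(log, "preprocess", "zero_sum_removed", sprintf("n=%d", sum(!keep)))
  expr_matrix(M$values[keep, , drop = FALSE], "RPKM",
              sample_meta = M$sample_meta)
}

#' log2(RPKM + 1) transform
#'
#' Transforms every cell and flips the unit state; applying it twice is an
#' error. The RPKM-scale per-gene means are carried along for the
#' low-expression filter.
#'
#' @param M An `expr_matrix` in RPKM units.
#' @return An `expr_matrix` in LOG2_RPKM_PLUS1 units.
#' @export
log_transform <- function(M) {
  stopifnot(inherits(M, "expr_matrix"))
  if (M$unit_state != "RPKM") stopf("matrix already log-transformed")
  expr_matrix(log2(M$values + 1), "LOG2_RPKM_PLUS1",
              sample_meta = M$sample_meta, rpkm_means = M$rpkm_means)
}

#' Filter genes with low mean expression
#'
#' Removes genes whose mean expression on the RPKM scale is below `threshold`
#' (default 0.3 RPKM). The mean is always taken on the RPKM scale, computed
#' before any log transform and carried on the object, so the filter can be
#' applied before or after [log_transform()]. The boundary is kept:
#' mean == threshold is retained.
#'
#' @param M An `expr_matrix`.
#' @param threshold Mean-RPKM cutoff, default 0.3.
#' @param log Optional run log.
#' @return Filtered `expr_matrix`.
#' @export
filter_low_expression <- function(M, threshold = 0.3, log = NULL) {
  stopifnot(inherits(M, "expr_matrix"))
  keep <- M$rpkm_means >= threshold
  if (!any(keep)) stopf("empty matrix: no gene reaches mean %g RPKM", threshold)
  log_event(log, "preprocess", "low_expression_removed",
            sprintf("n=%d threshold=%g", sum(!keep), threshold))
  out <- M
  out$values <- M$values[keep, , drop = FALSE]
  out$rpkm_means <- M$rpkm_means[keep]
  out
}

#' Subset an expression matrix to annotated genes
#'
#' Keeps the intersection of matrix genes and annotation rows; annotated genes
#' absent from the matrix are reported via the log (they are retained in the
#' annotation table itself as not-expressed).
#'
#' @param M An `expr_matrix`.
#' @param annotation A `gene_annotation` table.
#' @param log Optional run log.
#' @return Subset `expr_matrix`.
#' @export
subset_to_annotation <- function(M, annotation, log = NULL) {
  stopifnot(inherits(M, "expr_matrix"), inherits(annotation, "gene_annotation"))
  keep <- rownames(M$values) %in% annotation$gene
  if (!any(keep)) stopf("no annotated gene is present in the expression matrix")
  missing <- setdiff(annotation$gene, rownames(M$values))
  log_event(log, "preprocess", "not_expressed",
            sprintf("n=%d", length(missing)))
  out <- M
  out$values <- M$values[keep, , drop = FALSE]
  out$rpkm_means <- M$rpkm_means[keep]
  out
}

#' Per-gene QC descriptive statistics
#'
#' Mean, median and standard deviation per gene on the current scale, plus the
#' RPKM-scale mean and the keep/drop verdict of the 0.3-RPKM filter. Written to
#' the QC report by the pipeline; only the mean drives a decision.
#'
#' @param M An `expr_matrix`.
#' @param threshold Mean-RPKM cutoff used for the verdict column.
#' @return data.frame with one row per gene.
#' @export
qc_statistics <- function(M, threshold = 0.3) {
  v <- M$values
  data.frame(gene = rownames(v),
             mean = rowMeans(v),
             median = apply(v, 1L, stats::median),
             sd = apply(v, 1L, stats::sd),
             mean_rpkm = M$rpkm_means,
             kept = as.integer(M$rpkm_means >= threshold),
             reason = ifelse(M$rpkm_means >= threshold, "",
                             sprintf("mean_rpkm<%g", threshold)),
             stringsAsFactors = FALSE)
}

#' Flag sample outliers by hierarchical clustering
#'
#' Samples are clustered on Euclidean distance with average linkage; a sample
#' is flagged when it is still a singleton above the cut height (set at the
#' given quantile of merge heights). Report-only: no sample is removed.
#'
#' @param M An `expr_matrix` in LOG2_RPKM_PLUS1 units with >= 3 samples
#'   (fewer yields a warning and an empty report).
#' @param cut_height_quantile Quantile of merge heights used as the cut,
#'   default 0.95.
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
sample_outlier_report <- function(M, cut_height_quantile = 0.95) {
  stopifnot(inherits(M, "expr_matrix"))
  if (M$unit_state != "LOG2_RPKM_PLUS1")
    stopf("outlier report expects log-transformed values")
  n <- ncol(M$values)
  if (n < 3L) {
    warnf("outlier report needs >= 3 samples (got %d); empty report", n)
    return(character(0))
  }
  d <- stats::dist(t(M$values))
  if (max(d) == 0) return(character(0))
  hc <- stats::hclust(d, method = "average")
  cut <- stats::quantile(hc$height, cut_height_quantile, names = FALSE)
  labs <- stats::cutree(hc, h = cut)
  sizes <- table(labs)
  singletons <- names(sizes)[sizes == 1L]
  sort(colnames(M$values)[labs %in% as.integer(singletons)])
}

#' Write an expression matrix as TSV
#' @param M An `expr_matrix`.
#' @param path Output path.
#' @export
write_expression <- function(M, path) {
  df <- data.frame(gene = rownames(M$values), M$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_stable(df, path)
}
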