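# Internal helpers shared across the pipeline: TSV io with stable formatting
# (outputs must be byte-identical across runs) and a plain run-log collector.

#' @keywords internal
write_tsv_stable <- function(df, path) {
  # fixed 15-significant-digit formatting so checksums are reproducible
  fmt <- function(x) {
    if (is.numeric(x) && !is.integer(x)) {
      out <- formatC(x, digits = 15, format = "g")
      out[is.na(x)] <- "NA"
      out
    } else {
      x
    }
  }
  out <- as.data.frame(lapply(df, fmt), stringsAsFactors = FALSE,
                       check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' @keywords internal
read_tsv_plain <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

# A run log is an environment holding character lines: stage | event | detail.
# No timestamps: log files take part in the reproducibility checksums.

#' @keywords internal
new_run_log <- function() {
  env <- new.env(parent = emptyenv())
  env$lines <- character(0)
  env
}

#' @keywords internal
log_event <- function(log, stage, event, detail = "") {
  if (is.null(log)) return(invisible(NULL))
  log$lines <- c(log$lines, paste(stage, event, detail, sep = " | "))
  invisible(NULL)
}

#' @keywords internal
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @keywords internal
warnf <- function(...) warning(sprintf(...), call. = FALSE)
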