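# Gene-set curation: phenotype gene lists and the 22q13-region list are read
# from two-column TSV files, case-normalized, and merged into one multi-label
# annotation table over the union of all symbols.

#' Known gene-set labels
#'
#' The five neurological phenotype labels plus the chromosome-region label used
#' throughout the pipeline. User-defined extra labels are accepted everywhere;
#' this vector only fixes the canonical spelling of the built-in ones.
#'
#' @export
GENESET_LABELS <- c("ASD", "ID", "seizures", "hypotonia",
                    "language_impairment", "region_22q13")

#' Construct a gene set
#'
#' @param name Label of the set (one of [GENESET_LABELS] or a user-defined
#'   label).
#' @param genes Character vector of gene symbols; case-normalized to upper,
#'   de-duplicated.
#' @return An object of class `gene_set` with elements `name` and `genes`.
#' @export
gene_set <- function(name, genes) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- toupper(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stopf("gene set '%s': no genes", name)
  structure(list(name = name, genes = unique(genes)), class = "gene_set")
}

#' Load a gene set from a two-column TSV file
#'
#' Expected format: one gene symbol per line, optionally followed by a
#' tab-separated free-text source note. A header line whose first field is
#' `gene` (any case) is skipped. Symbols are upper-cased; duplicates after
#' case-normalization are logged, not fatal.
#'
#' @param path Path to the TSV file.
#' @param name Label to attach to the set.
#' @param alias A two-column data.frame (`from`, `to`) of symbol aliases applied
#'   before matching, or `NULL`.
#' @param log Optional run log (see [run_pipeline()]).
#' @return A `gene_set`.
#' @export
load_gene_set <- function(path, name, alias = NULL, log = NULL) {
  if (!file.exists(path)) stopf("gene set file not found: %s", path)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) && grepl("^gene(\t|$)", tolower(raw[1L]))) raw <- raw[-1L]
  if (length(raw) == 0L) stopf("%s: no genes parsed", path)
  fields <- strsplit(raw, "\t", fixed = TRUE)
  syms <- vapply(fields, `[[`, character(1), 1L)
  bad <- grep("\\s", trimws(syms))
  if (length(bad)) {
    stopf("%s: malformed symbol with embedded whitespace at line %d ('%s')",
          path, bad[1L], syms[bad[1L]])
  }
  syms <- toupper(trimws(syms))
  syms <- syms[nzchar(syms)]
  if (length(syms) == 0L) stopf("%s: no genes parsed", path)
  if (!is.null(alias)) {
    stopifnot(ncol(alias) >= 2L)
    from <- toupper(alias[[1L]]); to <- toupper(alias[[2L]])
    hit <- match(syms, from)
    syms[!is.na(hit)] <- to[hit[!is.na(hit)]]
  }
  n_dup <- length(syms) - length(unique(syms))
  if (n_dup > 0) {
    log_event(log, "curation", "duplicates_dropped",
              sprintf("set=%s n=%d", name, n_dup))
  }
  gene_set(name, syms)
}

#' Merge gene sets into a multi-label annotation table
#'
#' One row per gene in the union of all sets; one 0/1 column per set; a derived
#' `n_labels` column counting the flags. Sets may overlap (a gene can carry
#' several phenotype labels).
#'
#' @param sets A list of `gene_set` objects with unique names.
#' @return A data.frame of class `gene_annotation` with columns `gene`, one
#'   column per set (integer 0/1), and `n_labels`.
#' @export
build_annotation <- function(sets) {
  stopifnot(length(sets) >= 1L)
  nms <- vapply(sets, function(s) s$name, character(1))
  if (anyDuplicated(nms)) stopf("duplicate set names: %s",
                                paste(unique(nms[duplicated(nms)]), collapse = ", "))
  universe <- sort(unique(unlist(lapply(sets, `[[`, "genes"))))
  flags <- vapply(sets, function(s) as.integer(universe %in% s$genes),
                  integer(length(universe)))
  flags <- matrix(flags, nrow = length(universe),
                  dimnames = list(NULL, nms))
  out <- data.frame(gene = universe, flags, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$n_labels <- as.integer(rowSums(flags))
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Names of the gene-set columns of an annotation table
#' @param annotation A `gene_annotation` table.
#' @return Character vector of set names.
#' @export
annotation_sets <- function(annotation) {
  setdiff(colnames(annotation), c("gene", "n_labels"))
}

#' Genes carrying a given label
#' @param annotation A `gene_annotation` table.
#' @param set A set name present in the table.
#' @return Character vector of gene symbols.
#' @export
annotation_genes <- function(annotation, set) {
  if (!set %in% annotation_sets(annotation)) stopf("unknown set '%s'", set)
  annotation$gene[annotation[[set]] == 1L]
}

#' Write / read an annotation table as TSV (exact round-trip)
#' @param annotation A `gene_annotation` table.
#' @param path Output path.
#' @export
write_annotation <- function(annotation, path) {
  write_tsv_stable(as.data.frame(annotation), path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  df <- read_tsv_plain(path)
  stopifnot("gene" %in% colnames(df), "n_labels" %in% colnames(df))
  for (cc in setdiff(colnames(df), "gene")) df[[cc]] <- as.integer(df[[cc]])
  class(df) <- c("gene_annotation", "data.frame")
  df
}
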