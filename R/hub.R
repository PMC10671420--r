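# Hub-gene prioritization: intramodular degree-of-connectivity percentages on
# a thresholded within-module network, Cytoscape-ready edge/node exports, pLI
# ingestion, and the candidate table of region genes filtered by
# enriched-module membership and kME.

#' Resolve the edge-weight threshold for a module subnetwork
#'
#' Adaptive rule (default): the q-th quantile (default 0.9) of the module's
#' off-diagonal weights. Absolute rule: a fixed cutoff.
#'
#' @param W Weight matrix restricted to the module.
#' @param rule List: either `list(type = "quantile", q = 0.9)` or
#'   `list(type = "absolute", value = x)`.
#' @return Numeric threshold.
#' @keywords internal
edge_threshold <- function(W, rule) {
  type <- rule$type %||% "quantile"
  if (type == "quantile") {
    q <- rule$q %||% 0.9
    w <- W[upper.tri(W)]
    stats::quantile(w, q, names = FALSE)
  } else if (type == "absolute") {
    rule$value
  } else stopf("unknown edge threshold rule '%s'", type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Intramodular degree of connectivity (percent)
#'
#' Within each module's subnetwork an edge exists when its weight meets the
#' threshold; a gene's degree percentage is 100 x (number of within-module
#' neighbors) / (module size - 1), i.e. the percent of possible intramodular
#' partners.
#'
#' @param W Symmetric gene x gene weight matrix (TOM by default in the
#'   pipeline; adjacency via configuration).
#' @param partition A `module_partition`.
#' @param threshold_rule See [edge_threshold()]; or a single number treated as
#'   an absolute threshold.
#' @return Named numeric vector of degree percentages (grey genes NA;
#'   singleton modules 0 with a warning).
#' @export
intramodular_degree <- function(W, partition,
                                threshold_rule = list(type = "quantile", q = 0.9)) {
  if (is.numeric(threshold_rule))
    threshold_rule <- list(type = "absolute", value = threshold_rule)
  out <- stats::setNames(rep(NA_real_, length(partition$colors)),
                         names(partition$colors))
  for (m in module_colors(partition)) {
    genes <- names(partition$colors)[partition$colors == m]
    if (length(genes) == 1L) {
      warnf("module %s has a single gene; degree set to 0", m)
      out[genes] <- 0
      next
    }
    Wm <- W[genes, genes, drop = FALSE]
    thr <- edge_threshold(Wm, threshold_rule)
    adj <- Wm >= thr
    diag(adj) <- FALSE
    out[genes] <- 100 * rowSums(adj) / (length(genes) - 1L)
  }
  out
}

#' Export module edge lists and node attributes for visualization
#'
#' Per module, writes a weighted edge TSV (`gene_a  gene_b  weight  module`,
#' undirected with `gene_a < gene_b`), a SIF file (`gene_a co_expr gene_b`),
#' and one global node-attribute TSV carrying each gene's module, gene-set
#' labels and region flag for coloring in Cytoscape.
#'
#' @param W Symmetric weight matrix.
#' @param partition A `module_partition`.
#' @param annotation Optional `gene_annotation` for the node attributes.
#' @param out_dir Output directory (created if needed).
#' @param threshold_rule See [intramodular_degree()].
#' @param log Optional run log.
#' @return Invisible character vector of written file paths.
#' @export
export_edges <- function(W, partition, annotation = NULL, out_dir,
                         threshold_rule = list(type = "quantile", q = 0.9),
                         log = NULL) {
  if (is.numeric(threshold_rule))
    threshold_rule <- list(type = "absolute", value = threshold_rule)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (m in module_colors(partition)) {
    genes <- sort(names(partition$colors)[partition$colors == m])
    Wm <- W[genes, genes, drop = FALSE]
    thr <- edge_threshold(Wm, threshold_rule)
    idx <- which(upper.tri(Wm) & Wm >= thr, arr.ind = TRUE)
    ef <- file.path(out_dir, sprintf("edges_%s.tsv", m))
    sf <- file.path(out_dir, sprintf("edges_%s.sif", m))
    if (nrow(idx) == 0L) {
      warnf("module %s: no edge survives the threshold %.4g", m, thr)
      log_event(log, "export", "empty_edge_list", m)
      writeLines("gene_a\tgene_b\tweight\tmodule", ef)
      writeLines(character(0), sf)
    } else {
      df <- data.frame(gene_a = genes[idx[, 1L]], gene_b = genes[idx[, 2L]],
                       weight = Wm[idx], module = m, stringsAsFactors = FALSE)
      df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
      write_tsv_stable(df, ef)
      writeLines(sprintf("%s\tco_expr\t%s", df$gene_a, df$gene_b), sf)
    }
    written <- c(written, ef, sf)
  }
  nf <- file.path(out_dir, "node_attributes.tsv")
  nodes <- data.frame(gene = names(partition$colors),
                      module = unname(partition$colors),
                      stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    for (s in annotation_sets(annotation))
      nodes[[s]] <- as.integer(nodes$gene %in% annotation_genes(annotation, s))
    if ("region_22q13" %in% annotation_sets(annotation))
      nodes$region <- nodes$region_22q13
  }
  nodes <- nodes[order(nodes$gene), , drop = FALSE]
  write_tsv_stable(nodes, nf)
  invisible(c(written, nf))
}

#' Load a gene -> pLI table
#'
#' TSV with a gene column and a pLI column (named `pLI` or `pli`, or the
#' second column). Values must lie in \[0, 1\]; genes absent from the table
#' get NA downstream.
#'
#' @param path TSV path.
#' @return Named numeric vector of pLI scores.
#' @export
load_pli <- function(path) {
  df <- read_tsv_plain(path)
  gcol <- grep("^gene$", colnames(df), ignore.case = TRUE)[1L]
  pcol <- grep("^pli$", colnames(df), ignore.case = TRUE)[1L]
  if (is.na(gcol)) gcol <- 1L
  if (is.na(pcol)) pcol <- 2L
  pli <- as.numeric(df[[pcol]])
  bad <- which(!is.na(pli) & (pli < 0 | pli > 1))
  if (length(bad))
    stopf("pLI outside [0,1] for %s (%.3g)", df[[gcol]][bad[1L]], pli[bad[1L]])
  stats::setNames(pli, toupper(df[[gcol]]))
}

#' Assemble the candidate-gene table
#'
#' For each phenotype set: take its enriched modules; within them, keep the
#' region genes whose kME to their own module exceeds `kme_threshold`
#' (strictly); rank by degree percentage descending; attach pLI and the
#' `top_tier` flag (pLI > 0.9). A gene can appear under several phenotypes.
#' Phenotypes with no enriched module yield no rows and an explanatory note.
#'
#' @param annotation A `gene_annotation` including a `region_22q13` column.
#' @param partition A `module_partition`.
#' @param kME Genes x modules membership matrix.
#' @param degrees Named degree-percentage vector from [intramodular_degree()].
#' @param enrichment An `enrichment_result`.
#' @param pli Named pLI vector (or NULL: pLI column all NA).
#' @param kme_threshold Strict lower bound on own-module kME, default 0.7.
#' @param alpha Enrichment significance level, default 0.05.
#' @param use_adjusted Select enriched modules on BH q instead of raw p.
#' @param region_set Name of the region column, default `"region_22q13"`.
#' @param log Optional run log.
#' @return data.frame of class `candidate_table` with columns gene, phenotype,
#'   module, degree_pct, kme, pli, top_tier; attribute `notes` lists
#'   phenotypes without enriched modules.
#' @export
select_candidates <- function(annotation, partition, kME, degrees, enrichment,
                              pli = NULL, kme_threshold = 0.7, alpha = 0.05,
                              use_adjusted = FALSE,
                              region_set = "region_22q13", log = NULL) {
  if (!region_set %in% annotation_sets(annotation))
    stopf("annotation has no '%s' set", region_set)
  region_genes <- annotation_genes(annotation, region_set)
  phenos <- setdiff(annotation_sets(annotation), region_set)
  enr <- enriched_modules(enrichment, alpha, use_adjusted)
  own_kme <- own_module_kme(kME, partition)
  rows <- list()
  notes <- character(0)
  for (ph in phenos) {
    mods <- enr[[ph]]
    if (is.null(mods) || length(mods) == 0L) {
      notes <- c(notes, sprintf(
        "%s: no module enriched at alpha=%g; no candidates", ph, alpha))
      log_event(log, "prioritize", "no_enriched_module", ph)
      next
    }
    cand <- region_genes[region_genes %in% names(partition$colors)]
    cand <- cand[partition$colors[cand] %in% mods]
    cand <- cand[!is.na(own_kme[cand]) & own_kme[cand] > kme_threshold]
    if (!length(cand)) next
    df <- data.frame(gene = cand,
                     phenotype = ph,
                     module = unname(partition$colors[cand]),
                     degree_pct = unname(degrees[cand]),
                     kme = unname(own_kme[cand]),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$degree_pct, df$gene), , drop = FALSE]
    rows[[length(rows) + 1L]] <- df
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), phenotype = character(0),
               module = character(0), degree_pct = numeric(0),
               kme = numeric(0), stringsAsFactors = FALSE)
  out$pli <- if (is.null(pli)) NA_real_ else unname(pli[out$gene])
  out$top_tier <- !is.na(out$pli) & out$pli > 0.9
  rownames(out) <- NULL
  attr(out, "notes") <- notes
  class(out) <- c("candidate_table", "data.frame")
  out
}
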