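# Module detection: average-linkage hierarchical clustering of the TOM
# dissimilarity, tree cut into modules (static height cut or a recursive
# branch-gap cut), module eigengenes (first principal component of the
# standardized module expression), eigengene-based module merging, and kME
# module membership.

# Standard module color sequence (largest module first); "grey" is reserved
# for unassigned genes. Beyond the list, modules are named "module_<i>".
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
  "darkolivegreen", "darkmagenta", "sienna3", "yellowgreen", "skyblue3",
  "plum1", "orangered4", "mediumpurple3", "lightsteelblue1", "lightcyan1",
  "ivory", "floralwhite", "darkorange2", "brown4", "bisque4", "darkslateblue",
  "plum2", "thistle2")

#' Hierarchical clustering of a dissimilarity matrix
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal.
#' @param linkage Agglomeration method, default `"average"` (UPGMA).
#' @return An `hclust` object.
#' @export
hierarchical_cluster <- function(D, linkage = "average") {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-8) stopf("dissimilarity matrix is not symmetric")
  stats::hclust(stats::as.dist(D), method = linkage)
}

#' Cut a dendrogram into modules
#'
#' Two cut methods. `static`: clusters are the connected components below
#' `cut_height`; clusters smaller than `min_module_size` become grey
#' (unassigned). `dynamic_branch`: the tree is descended from the root and a
#' branch is accepted as a module when it holds at least `min_module_size`
#' leaves and its merge-height gap — the height at which it joins the rest of
#' the tree minus its own top merge height — exceeds `gap_frac` times the
#' branch's internal height spread (top minus lowest merge height inside the
#' branch; a branch with no spread is accepted on any positive gap). Descent
#' stops at the first accepted branch and the remaining leaves are grey; a
#' tight module that comes out split is fused later by eigengene merging. On
#' TOM dissimilarity trees, where merge heights compress toward 1, this
#' branch-relative gap separates planted modules from incidental background
#' joins far more sharply than a gap measured against the total tree height.
#'
#' @param dendro An `hclust` object.
#' @param method `"dynamic_branch"` (default) or `"static"`.
#' @param cut_height Height for the static cut; must lie in
#'   \[0, max merge height\].
#' @param min_module_size Minimum module size, default 30.
#' @param gap_frac Branch-gap fraction for the dynamic cut, default 0.005.
#' @return A `module_partition`: list with `labels` (named integer vector,
#'   0 = grey), `colors` (named character vector per gene), `module_sizes`
#'   (named by color).
#' @export
cut_modules <- function(dendro, method = c("dynamic_branch", "static"),
                        cut_height = NULL, min_module_size = 30L,
                        gap_frac = 0.005) {
  method <- match.arg(method)
  stopifnot(inherits(dendro, "hclust"), min_module_size >= 2L)
  n <- length(dendro$order)
  H <- max(dendro$height)
  if (method == "static") {
    if (is.null(cut_height)) cut_height <- 0.99 * H
    if (cut_height < 0 || cut_height > H)
      stopf("cut_height %g outside [0, %g]", cut_height, H)
    raw <- static_cut(dendro, cut_height)
    labels <- relabel_min_size(raw, min_module_size)
  } else {
    labels <- dynamic_branch_cut(dendro, min_module_size, gap_frac)
  }
  names(labels) <- dendro$labels
  assign_colors(new_partition(labels))
}

# connected components of merges at or below the cut height; tolerant of the
# tied / non-monotone merge heights average linkage can produce
static_cut <- function(dendro, cut_height) {
  m <- dendro$merge
  h <- dendro$height
  n <- length(dendro$order)
  comp <- seq_len(n)          # union-find over leaves, path-compressed lazily
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  node_rep <- integer(nrow(m))
  for (i in seq_len(nrow(m))) {
    reps <- vapply(m[i, ], function(c)
      if (c < 0) find(-c) else find(node_rep[c]), integer(1))
    if (h[i] <= cut_height) comp[reps[2L]] <- reps[1L]
    node_rep[i] <- reps[1L]
  }
  labs <- vapply(seq_len(n), find, integer(1))
  match(labs, unique(labs))
}

# drop clusters below the minimum size to grey (0) and renumber by size
relabel_min_size <- function(raw, min_module_size) {
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  out <- integer(length(raw))
  nxt <- 1L
  for (cl in keep) {
    out[raw == cl] <- nxt
    nxt <- nxt + 1L
  }
  out
}

# Top-down branch-gap cut. Merge node i of hclust joins children given by
# merge[i, ]: negative entries are leaves, positive are earlier merges. A
# branch is accepted as a module when it is large enough and the gap between
# the height at which it joins the rest of the tree and its own top merge
# height is large relative to its internal height spread; descent stops at the
# first accepted branch, so tight branches come out whole (sub-structure is
# handled later by eigengene merging).
dynamic_branch_cut <- function(dendro, min_module_size, gap_frac) {
  m <- dendro$merge
  h <- dendro$height
  n <- length(dendro$order)
  n_merge <- nrow(m)
  leaves <- vector("list", n_merge)   # leaf sets per merge node, bottom-up
  minh <- numeric(n_merge)            # lowest merge height within the branch
  for (i in seq_len(n_merge)) {
    ch <- m[i, ]
    lv <- integer(0); mh <- h[i]
    for (c in ch) {
      if (c < 0) lv <- c(lv, -c)
      else { lv <- c(lv, leaves[[c]]); mh <- min(mh, minh[c]) }
    }
    leaves[[i]] <- lv
    minh[i] <- mh
  }
  eps <- .Machine$double.eps^0.5
  modules <- list()
  visit <- function(node, parent_height) {
    if (node < 0) return(invisible(NULL))
    if (length(leaves[[node]]) < min_module_size) return(invisible(NULL))
    if (!is.na(parent_height)) {
      gap <- parent_height - h[node]
      spread <- h[node] - minh[node]
      accept <- gap > eps && (spread < eps || gap / spread >= gap_frac)
      if (accept) {
        modules[[length(modules) + 1L]] <<- leaves[[node]]
        return(invisible(NULL))
      }
    }
    for (ch in m[node, ]) visit(ch, h[node])
    invisible(NULL)
  }
  visit(n_merge, NA_real_)
  out <- integer(n)
  for (i in seq_along(modules)) out[modules[[i]]] <- i
  out
}

new_partition <- function(labels) {
  structure(list(labels = labels, colors = NULL, module_sizes = NULL),
            class = "module_partition")
}

#' Assign the standard color sequence to modules
#'
#' Modules are sorted by size descending (ties broken by the smallest member
#' gene symbol) and given the standard palette; unassigned genes are grey.
#'
#' @param partition A `module_partition`.
#' @return The partition with `colors` and `module_sizes` filled in.
#' @export
assign_colors <- function(partition) {
  labels <- partition$labels
  ids <- setdiff(sort(unique(labels)), 0L)
  if (length(ids)) {
    sizes <- vapply(ids, function(i) sum(labels == i), integer(1))
    firsts <- vapply(ids, function(i) min(names(labels)[labels == i]),
                     character(1))
    ord <- ids[order(-sizes, firsts)]
    cols <- c(MODULE_COLORS, sprintf("module_%d", seq_len(max(0, length(ord) -
                length(MODULE_COLORS))) + length(MODULE_COLORS)))
    colmap <- stats::setNames(cols[seq_along(ord)], ord)
  } else {
    colmap <- character(0)
  }
  colors <- rep("grey", length(labels))
  nz <- labels != 0L
  colors[nz] <- colmap[as.character(labels[nz])]
  names(colors) <- names(labels)
  partition$colors <- colors
  sz <- table(colors[colors != "grey"])
  partition$module_sizes <- stats::setNames(as.integer(sz), names(sz))
  partition
}

#' @export
print.module_partition <- function(x, ...) {
  ng <- sum(x$colors == "grey")
  cat(sprintf("module_partition: %d modules over %d genes (%d grey)\n",
              length(x$module_sizes), length(x$labels), ng))
  if (length(x$module_sizes)) {
    sz <- sort(x$module_sizes, decreasing = TRUE)
    cat(paste(sprintf("%s=%d", names(sz), sz), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Module colors present in a partition (grey excluded)
#' @param partition A `module_partition`.
#' @return Character vector, largest module first.
#' @export
module_colors <- function(partition) {
  names(sort(partition$module_sizes, decreasing = TRUE))
}

#' Module eigengenes
#'
#' Per module, the gene expression submatrix is standardized per gene (zero
#' mean, unit sd over samples) and the first right-singular vector is taken as
#' the eigengene: one value per sample, unit norm, sign-aligned so that its
#' correlation with the module's mean standardized profile is non-negative
#' (when that profile is constant the first gene is used as the reference).
#'
#' @param M An `expr_matrix` (log scale) or plain genes x samples matrix.
#' @param partition A `module_partition` over the same genes.
#' @return List of class `eigengene_matrix`: `ME` (modules x samples, rownames
#'   = module colors), `var_explained` (named fraction per module).
#' @export
module_eigengenes <- function(M, partition) {
  v <- if (inherits(M, "expr_matrix")) M$values else M
  cols <- module_colors(partition)
  if (!length(cols)) stopf("partition has no modules")
  ME <- matrix(NA_real_, length(cols), ncol(v),
               dimnames = list(cols, colnames(v)))
  ve <- stats::setNames(numeric(length(cols)), cols)
  for (cl in cols) {
    genes <- names(partition$colors)[partition$colors == cl]
    X <- v[genes, , drop = FALSE]
    sds <- apply(X, 1L, stats::sd)
    if (any(sds == 0))
      stopf("module %s contains zero-variance gene(s)", cl)
    Xs <- t(scale(t(X)))
    sv <- svd(Xs, nu = 0, nv = 1)
    e <- sv$v[, 1L]
    # align with the mean standardized profile; if that profile is constant
    # (e.g. genes in exact opposition), fall back to the first gene
    a <- suppressWarnings(stats::cor(e, colMeans(Xs)))
    if (is.na(a)) a <- suppressWarnings(stats::cor(e, Xs[1L, ]))
    if (!is.na(a) && a < 0) e <- -e
    ME[cl, ] <- e
    ve[cl] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  structure(list(ME = ME, var_explained = ve), class = "eigengene_matrix")
}

#' Merge modules with correlated eigengenes
#'
#' Modules are clustered (average linkage) on `1 - cor(ME)`; clusters whose
#' merge height falls below `merge_cut_height` are fused, eigengenes are
#' recomputed, and the procedure iterates until no merge occurs.
#'
#' @param M Expression (`expr_matrix` or matrix) used to recompute eigengenes.
#' @param partition A `module_partition`.
#' @param ME An `eigengene_matrix` for the partition.
#' @param merge_cut_height Dissimilarity cut, default 0.25 (eigengene
#'   correlation 0.75).
#' @param log Optional run log.
#' @return List with the merged `partition` and recomputed `ME`.
#' @export
merge_close_modules <- function(M, partition, ME, merge_cut_height = 0.25,
                                log = NULL) {
  repeat {
    cols <- rownames(ME$ME)
    if (length(cols) < 2L) break
    d <- 1 - stats::cor(t(ME$ME))
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    grp <- stats::cutree(hc, h = merge_cut_height)
    if (max(grp) == length(cols)) break   # nothing below the cut
    log_event(log, "modules", "eigengene_merge",
              sprintf("%d -> %d modules", length(cols), max(grp)))
    labels <- integer(length(partition$labels))
    names(labels) <- names(partition$labels)
    for (g in seq_len(max(grp))) {
      members <- cols[grp == g]
      labels[partition$colors %in% members] <- g
    }
    partition <- assign_colors(new_partition(labels))
    ME <- module_eigengenes(M, partition)
  }
  list(partition = partition, ME = ME)
}

#' Module membership (kME)
#'
#' Pearson correlation between every gene's expression profile and every
#' module eigengene.
#'
#' @param M Expression (`expr_matrix` or matrix).
#' @param ME An `eigengene_matrix`.
#' @return Genes x modules matrix of correlations in \[-1, 1\].
#' @export
module_membership <- function(M, ME) {
  v <- if (inherits(M, "expr_matrix")) M$values else M
  stopifnot(ncol(v) == ncol(ME$ME))
  kme <- stats::cor(t(v), t(ME$ME))
  dimnames(kme) <- list(rownames(v), rownames(ME$ME))
  kme
}

#' kME of each gene to its own module
#'
#' @param kME Genes x modules membership matrix.
#' @param partition A `module_partition`.
#' @return Named numeric vector; NA for grey genes.
#' @export
own_module_kme <- function(kME, partition) {
  out <- stats::setNames(rep(NA_real_, length(partition$colors)),
                         names(partition$colors))
  for (cl in colnames(kME)) {
    g <- names(partition$colors)[partition$colors == cl]
    out[g] <- kME[g, cl]
  }
  out
}
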