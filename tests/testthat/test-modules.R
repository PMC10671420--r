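block_dissimilarity <- function(sizes, within = 0.1, between = 0.9) {
  n <- sum(sizes)
  D <- matrix(between, n, n)
  stops <- cumsum(sizes); starts <- c(1, head(stops, -1) + 1)
  for (b in seq_along(sizes)) {
    ix <- starts[b]:stops[b]
    D[ix, ix] <- within
  }
  diag(D) <- 0
  dimnames(D) <- list(sprintf("G%03d", 1:n), sprintf("G%03d", 1:n))
  D
}

test_that("average-linkage clustering resolves well-separated blocks", {
  D <- block_dissimilarity(c(2, 2))
  hc <- hierarchical_cluster(D)
  expect_equal(sort(hc$height), c(0.1, 0.1, 0.9), tolerance = 1e-12)

  expect_equal(length(hierarchical_cluster(block_dissimilarity(2))$height), 1L)
  allz <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(hierarchical_cluster(allz)$height == 0))

  bad <- block_dissimilarity(c(2, 2)); bad[1, 2] <- 0.5
  expect_error(hierarchical_cluster(bad), "not symmetric")
})

test_that("tree cut recovers planted blocks and respects the size floor", {
  D <- block_dissimilarity(c(40, 40, 40))
  hc <- hierarchical_cluster(D)
  part <- cut_modules(hc, min_module_size = 30)
  expect_equal(sort(unname(part$module_sizes)), c(40L, 40L, 40L))
  expect_equal(sum(part$colors == "grey"), 0L)

  all_grey <- cut_modules(hc, min_module_size = 50)
  expect_length(all_grey$module_sizes, 0L)
  expect_true(all(all_grey$colors == "grey"))

  # static cut at 0: every gene a singleton, all grey at min size >= 2
  static0 <- cut_modules(hc, method = "static", cut_height = 0,
                         min_module_size = 2)
  expect_true(all(static0$colors == "grey"))

  expect_error(cut_modules(hc, method = "static", cut_height = 2),
               "outside")
})

test_that("static and dynamic cuts agree on clean block structure", {
  D <- block_dissimilarity(c(35, 45), within = 0.2, between = 0.95)
  hc <- hierarchical_cluster(D)
  stat <- cut_modules(hc, method = "static", cut_height = 0.5,
                      min_module_size = 30)
  dyn <- cut_modules(hc, min_module_size = 30)
  expect_equal(stat$colors, dyn$colors)
  expect_equal(sort(unname(stat$module_sizes)), c(35L, 45L))
})

test_that("module colors follow the size-ordered standard palette", {
  labels <- c(rep(1L, 60), rep(2L, 100), rep(3L, 80), rep(0L, 5))
  names(labels) <- sprintf("G%03d", seq_along(labels))
  part <- assign_colors(structure(list(labels = labels),
                                  class = "module_partition"))
  expect_equal(unname(part$colors[61]), "turquoise")  # size 100
  expect_equal(unname(part$colors[161]), "blue")      # size 80
  expect_equal(unname(part$colors[1]), "brown")       # size 60
  expect_equal(unname(part$colors[241]), "grey")
  # equal sizes: deterministic tie-break by smallest member symbol
  lab2 <- c(rep(2L, 10), rep(1L, 10))
  names(lab2) <- c(sprintf("B%02d", 1:10), sprintf("A%02d", 1:10))
  p2 <- assign_colors(structure(list(labels = lab2),
                                class = "module_partition"))
  expect_equal(unname(p2$colors[names(p2$colors) == "A01"]), "turquoise")
})

test_that("eigengene of a rank-1 module is the profile itself", {
  prof <- rnorm(30)
  v <- matrix(rep(prof, each = 10), 10, 30,
              dimnames = list(sprintf("G%02d", 1:10), sprintf("S%02d", 1:30)))
  v <- v + 0 # identical rows
  labels <- setNames(rep(1L, 10), rownames(v))
  part <- assign_colors(structure(list(labels = labels),
                                  class = "module_partition"))
  ME <- module_eigengenes(v, part)
  expect_equal(unname(ME$var_explained), 1, tolerance = 1e-12)
  expect_equal(abs(cor(ME$ME[1, ], prof)), 1, tolerance = 1e-12)
  expect_equal(sum(ME$ME[1, ]^2), 1)  # unit norm
  # sign aligned with the mean standardized profile
  expect_gte(cor(ME$ME[1, ], scale(prof)[, 1]), 0)
})

test_that("two exactly opposite genes give explained variance 1", {
  prof <- rnorm(40)
  v <- rbind(UP = prof, DOWN = -prof)
  colnames(v) <- sprintf("S%02d", 1:40)
  part <- assign_colors(structure(
    list(labels = setNames(c(1L, 1L), rownames(v))),
    class = "module_partition"))
  ME <- module_eigengenes(v, part)
  expect_equal(unname(ME$var_explained), 1, tolerance = 1e-12)
})

test_that("eigengene recovers the generating latent factor", {
  set.seed(42)
  n <- 200
  e <- rnorm(n)
  lam <- 0.9
  v <- t(sapply(1:30, function(g) lam * e + sqrt(1 - lam^2) * rnorm(n)))
  dimnames(v) <- list(sprintf("G%02d", 1:30), sprintf("S%03d", 1:n))
  part <- assign_colors(structure(
    list(labels = setNames(rep(1L, 30), rownames(v))),
    class = "module_partition"))
  ME <- module_eigengenes(v, part)
  expect_gte(cor(ME$ME[1, ], e)^2, 0.95)
})

test_that("eigengenes are invariant to flipping one gene's sign", {
  set.seed(8)
  v <- planted_blocks(2, 15, 50, loading = 0.8)
  labels <- setNames(rep(1:2, each = 15), rownames(v))
  part <- assign_colors(structure(list(labels = labels),
                                  class = "module_partition"))
  ME1 <- module_eigengenes(v, part)
  v2 <- v; v2[4, ] <- -v2[4, ]
  ME2 <- module_eigengenes(v2, part)
  expect_equal(abs(ME1$ME), abs(ME2$ME), tolerance = 1e-9)
  expect_equal(ME1$var_explained, ME2$var_explained, tolerance = 1e-12)
})

test_that("modules with correlated eigengenes are merged to a fixpoint", {
  set.seed(99)
  n <- 80
  e1 <- rnorm(n); e2 <- rnorm(n)
  mk <- function(e, sz, lam = 0.95)
    t(sapply(seq_len(sz), function(g) lam * e + sqrt(1 - lam^2) * rnorm(n)))
  # modules 1 and 2 share a latent factor; module 3 is independent
  v <- rbind(mk(e1, 12), mk(e1, 10), mk(e2, 14))
  dimnames(v) <- list(sprintf("G%02d", 1:36), sprintf("S%03d", 1:n))
  labels <- setNames(rep(1:3, c(12, 10, 14)), rownames(v))
  part <- assign_colors(structure(list(labels = labels),
                                  class = "module_partition"))
  ME <- module_eigengenes(v, part)
  merged <- merge_close_modules(v, part, ME, merge_cut_height = 0.25)
  expect_length(merged$partition$module_sizes, 2L)
  sz <- sort(unname(merged$partition$module_sizes))
  expect_equal(sz, c(14L, 22L))

  # independent eigengenes stay apart
  part3 <- assign_colors(structure(
    list(labels = setNames(rep(1:2, c(12, 14)), rownames(v)[c(1:12, 23:36)])),
    class = "module_partition"))
  ME3 <- module_eigengenes(v[c(1:12, 23:36), ], part3)
  kept <- merge_close_modules(v[c(1:12, 23:36), ], part3, ME3, 0.25)
  expect_length(kept$partition$module_sizes, 2L)

  # three modules all driven by one factor collapse to one in a single pass
  v4 <- rbind(mk(e1, 10), mk(e1, 10), mk(e1, 10))
  dimnames(v4) <- list(sprintf("H%02d", 1:30), sprintf("S%03d", 1:n))
  p4 <- assign_colors(structure(
    list(labels = setNames(rep(1:3, each = 10), rownames(v4))),
    class = "module_partition"))
  m4 <- merge_close_modules(v4, p4, module_eigengenes(v4, p4), 0.25)
  expect_length(m4$partition$module_sizes, 1L)
  expect_equal(unname(m4$partition$module_sizes), 30L)
})

test_that("kME is the gene-eigengene correlation", {
  set.seed(3)
  v <- planted_blocks(1, 10, 500, loading = 0.8, n_noise = 1)
  part <- assign_colors(structure(
    list(labels = setNames(c(rep(1L, 10), 0L), rownames(v))),
    class = "module_partition"))
  ME <- module_eigengenes(v, part)
  kme <- module_membership(v, ME)
  # a gene equal to the eigengene itself has kME 1
  v2 <- rbind(v, EXACT = ME$ME[1, ])
  kme2 <- module_membership(v2, ME)
  expect_equal(unname(kme2["EXACT", 1]), 1, tolerance = 1e-12)
  # pure-noise gene at n = 500 has |kME| < 0.2
  expect_lt(abs(kme["N01", 1]), 0.2)
  # own-module extraction
  own <- own_module_kme(kme, part)
  expect_true(all(own[sprintf("B1G%02d", 1:10)] > 0.5))
  expect_true(is.na(own["N01"]))
})
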