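test_that("similarity reproduces closed forms in both modes", {
  # two profiles with correlation exactly -0.5
  x <- c(1, 0, -1, 0)
  y <- c(-1, 0, 0, 1) # cor(x, y) = -sum/...: verify numerically below
  v <- rbind(a = x, b = y)
  colnames(v) <- sprintf("S%d", 1:4)
  r <- cor(x, y)
  expect_equal(unname(similarity(v, "unsigned_abs")["a", "b"]), abs(r))
  expect_equal(unname(similarity(v, "signed_shift")["a", "b"]), (1 + r) / 2)
  expect_equal(unname(diag(similarity(v))), c(1, 1))

  # a gene against itself is 1 in both modes
  v2 <- rbind(g = rnorm(10), g2 = rnorm(10))
  colnames(v2) <- sprintf("S%d", 1:10)
  expect_equal(unname(diag(similarity(v2, "signed_shift"))), c(1, 1))
})

test_that("similarity matches the naive two-pass correlation loop", {
  set.seed(101)
  v <- matrix(rnorm(300), 10, 30,
              dimnames = list(sprintf("G%02d", 1:10), sprintf("S%02d", 1:30)))
  S <- similarity(v)
  expect_lt(max(abs(S - naive_similarity(v))), 1e-12)
  Ss <- similarity(v, "signed_shift")
  expect_lt(max(abs(Ss - naive_similarity(v, "signed_shift"))), 1e-12)
})

test_that("similarity refuses zero-variance genes, naming them", {
  v <- rbind(FLAT = rep(2, 8), OK = rnorm(8))
  colnames(v) <- sprintf("S%d", 1:8)
  expect_error(similarity(v), "FLAT")
})

test_that("adjacency is the element-wise power with validated beta", {
  S <- matrix(c(1, 0.5, 0, 0.5, 1, 1, 0, 1, 1), 3, 3)
  A <- adjacency(S, 9)
  expect_identical(A[1, 2], 0.001953125)   # 0.5^9 = 1/512
  expect_identical(A[1, 3], 0)
  expect_identical(A[2, 3], 1)
  expect_error(adjacency(S, 0), "positive integer")
  expect_error(adjacency(S, 2.5), "positive integer")
})

test_that("beta powering strictly shrinks sub-unit weights and connectivity", {
  set.seed(5)
  v <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("G%02d", 1:20), sprintf("S%02d", 1:10)))
  S <- similarity(v)
  off <- upper.tri(S)
  inside <- S[off] > 0 & S[off] < 1
  k_prev <- connectivity(adjacency(S, 1))
  a_prev <- adjacency(S, 1)[off]
  for (b in 2:6) {
    A <- adjacency(S, b)
    expect_true(all(A[off][inside] < a_prev[inside]))
    k <- connectivity(A)
    expect_true(all(k <= k_prev + 1e-12))
    a_prev <- A[off]; k_prev <- k
  }
})

test_that("TOM reproduces hand-computed graphs and the triple-loop oracle", {
  # triangle with unit edges: complete shared neighborhoods
  tri <- matrix(1, 3, 3)
  Tt <- topological_overlap(tri)
  expect_equal(unname(Tt[upper.tri(Tt)]), rep(1, 3))

  # path 1-2-3 with unit edges: T(1,3) = (1 + 0) / (1 + 1 - 0) = 0.5
  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 1] <- 1
  path[2, 3] <- path[3, 2] <- 1; diag(path) <- 1
  Tp <- topological_overlap(path)
  expect_equal(Tp[1, 3], 0.5)

  set.seed(77)
  for (rep in 1:5) {
    S <- abs(cor(matrix(rnorm(12 * 30), 30, 12)))
    A <- S^4; diag(A) <- 1
    expect_lt(max(abs(topological_overlap(A) - naive_tom(A))), 1e-12)
  }
})

test_that("TOM entries stay within [0, 1] for random adjacencies", {
  set.seed(13)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    A <- matrix(runif(n * n), n, n)
    A <- (A + t(A)) / 2; diag(A) <- 1
    Tm <- topological_overlap(A)
    expect_true(all(Tm >= 0 & Tm <= 1))
    expect_equal(Tm, t(Tm))
  }
})

test_that("network transforms are equivariant under gene relabeling", {
  set.seed(23)
  v <- matrix(rnorm(15 * 25), 15, 25,
              dimnames = list(sprintf("G%02d", 1:15), sprintf("S%02d", 1:25)))
  perm <- sample(15)
  S <- similarity(v)
  Sp <- similarity(v[perm, ])
  expect_equal(unname(Sp), unname(S[perm, perm]), ignore_attr = TRUE)
  Tm <- topological_overlap(adjacency(S, 6))
  Tp <- topological_overlap(adjacency(Sp, 6))
  expect_equal(unname(Tp), unname(Tm[perm, perm]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("scale-free fit scores a power law high and flags degenerate input", {
  set.seed(555)
  pk <- (1:100)^-2
  k <- sample(1:100, 5000, replace = TRUE, prob = pk / sum(pk))
  fit <- scale_free_fit(k)
  expect_false(fit$degenerate)
  expect_gte(fit$r2, 0.8)
  expect_lt(fit$slope, 0)

  flat <- scale_free_fit(rep(3.2, 50))
  expect_true(flat$degenerate)
  expect_identical(flat$r2, 0)

  # inverted law: frequency increasing with k -> negative signed R2
  k_inv <- sample(1:100, 5000, replace = TRUE, prob = (1:100) / sum(1:100))
  expect_lt(scale_free_fit(k_inv)$r2, 0)
})

small_benchmark_similarity <- function() {
  spec <- synthetic_spec(
    n_samples = 80,
    modules = rep(list(list(size = 30, loading = c(0.5, 0.9))), 4),
    n_background = 60, n_near_zero = 0, hub = NULL,
    set_plants = list(), region_plants = list(), seed = 303)
  similarity(log_transform(simulate_expression(spec)$expression)$values)
}

test_that("soft-threshold pick takes the smallest passing power", {
  S <- small_benchmark_similarity()
  rep_ <- pick_soft_threshold(S, candidates = 1:12, target_r2 = 0.8)
  expect_s3_class(rep_, "soft_threshold_report")
  expect_false(rep_$fallback_used)
  first_pass <- min(rep_$table$beta[!rep_$table$degenerate &
                                      rep_$table$r2 >= 0.8])
  expect_identical(rep_$chosen_beta, as.integer(first_pass))
  # mean connectivity non-increasing in beta, agreeing with brute force
  expect_true(all(diff(rep_$table$mean_k) <= 1e-10))
  for (b in c(1, 6)) {
    A <- S^b; diag(A) <- 1
    brute <- mean(rowSums(A) - 1)
    expect_equal(rep_$table$mean_k[rep_$table$beta == b], brute,
                 tolerance = 1e-12)
  }
})

test_that("identity-like similarity falls back to the configured power", {
  S <- diag(30)
  expect_warning(rep_ <- pick_soft_threshold(S), "falling back to beta = 9")
  expect_true(rep_$fallback_used)
  expect_identical(rep_$chosen_beta, 9L)
  expect_true(all(rep_$table$degenerate))
})

test_that("a single passing candidate is a forced choice", {
  S <- small_benchmark_similarity()
  rep_ <- pick_soft_threshold(S, candidates = 9, target_r2 = 0.8)
  expect_false(rep_$fallback_used)
  expect_identical(rep_$chosen_beta, 9L)
})
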