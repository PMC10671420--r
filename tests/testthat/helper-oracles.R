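# Independent brute-force oracles used to check the matrix implementations,
# plus small fixture builders. These stay deliberately naive (scalar loops,
# closed-form enumeration) so they share no code path with the package.

naive_pearson <- function(x, y) {
  # two-pass scalar correlation
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

naive_similarity <- function(v, mode = "unsigned_abs") {
  n <- nrow(v)
  S <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r <- naive_pearson(v[i, ], v[j, ])
    S[i, j] <- if (mode == "unsigned_abs") abs(r) else (1 + r) / 2
  }
  S
}

naive_tom <- function(A) {
  n <- nrow(A)
  Tm <- matrix(0, n, n)
  k <- numeric(n)
  for (i in seq_len(n)) for (u in seq_len(n)) if (u != i) k[i] <- k[i] + A[i, u]
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { Tm[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    Tm[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  Tm
}

# one-sided (greater) Fisher p by enumerating the hypergeometric support
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b          # module size (draws)
  K <- a + c          # set size (successes in urn)
  N <- a + b + c + d
  lo <- max(0, m + K - N); hi <- min(m, K)
  probs <- vapply(lo:hi, function(x)
    choose(K, x) * choose(N - K, m - x) / choose(N, m), numeric(1))
  sum(probs[(lo:hi) >= a])
}

naive_degree_pct <- function(W, genes, thr) {
  out <- numeric(length(genes))
  names(out) <- genes
  for (g in genes) {
    cnt <- 0
    for (h in genes) if (h != g && W[g, h] >= thr) cnt <- cnt + 1
    out[g] <- 100 * cnt / (length(genes) - 1)
  }
  out
}

# quick log-scale matrix with planted rank-1 blocks (no RPKM round trip)
planted_blocks <- function(n_blocks, block_size, n_samples, loading = 1,
                           n_noise = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (b in seq_len(n_blocks)) {
    e <- rnorm(n_samples)
    X <- matrix(NA_real_, block_size, n_samples)
    for (g in seq_len(block_size))
      X[g, ] <- loading * e + sqrt(1 - loading^2) * rnorm(n_samples)
    rownames(X) <- sprintf("B%dG%02d", b, seq_len(block_size))
    rows[[b]] <- X
  }
  X <- do.call(rbind, rows)
  if (n_noise > 0) {
    Z <- matrix(rnorm(n_noise * n_samples), n_noise, n_samples)
    rownames(Z) <- sprintf("N%02d", seq_len(n_noise))
    X <- rbind(X, Z)
  }
  colnames(X) <- sprintf("S%03d", seq_len(n_samples))
  X
}

write_geneset_file <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
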