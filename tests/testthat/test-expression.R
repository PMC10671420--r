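make_rpkm <- function(values, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expr_matrix(values, "RPKM")
}

test_that("load_expression reads a plain TSV and rejects bad values", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3\ts4",
               "A\t1\t2\t3\t4", "B\t0\t0\t1\t0", "C\t5\t5\t5\t5"), p)
  M <- load_expression(p)
  expect_equal(dim(M), c(3L, 4L))
  expect_equal(M$unit_state, "RPKM")
  expect_setequal(gene_ids(M), c("A", "B", "C"))

  p2 <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "A\t1\t-1.0"), p2)
  expect_error(load_expression(p2), "negative")
})

test_that("load_expression reads the three-file dialect with sample metadata", {
  base <- tempfile(); dir.create(base)
  genes <- sprintf("GENE%02d", 1:10)
  set.seed(4)
  vals <- matrix(round(runif(60, 0, 50), 3), 10, 6)
  write.table(cbind(1:10, vals), file.path(base, "expression_matrix.csv"),
              sep = ",", row.names = FALSE, col.names = FALSE)
  write.csv(data.frame(row_num = 1:10, gene_symbol = genes),
            file.path(base, "rows_metadata.csv"), row.names = FALSE)
  write.csv(data.frame(column_num = 1:6, age = paste0(c(8, 12, 16, 21, 35, 37), " pcw"),
                       structure_name = "DFC"),
            file.path(base, "columns_metadata.csv"), row.names = FALSE)
  M <- load_expression(file.path(base, "expression_matrix.csv"),
                       file.path(base, "rows_metadata.csv"),
                       file.path(base, "columns_metadata.csv"))
  expect_equal(dim(M), c(10L, 6L))
  expect_equal(gene_ids(M), genes)
  expect_equal(M$sample_meta$age[1], "8 pcw")
  expect_equal(M$sample_meta$structure_name[3], "DFC")
  # mismatched metadata is an error
  write.csv(data.frame(gene_symbol = genes[1:5]),
            file.path(base, "rows_metadata.csv"), row.names = FALSE)
  expect_error(load_expression(file.path(base, "expression_matrix.csv"),
                               file.path(base, "rows_metadata.csv")),
               "does not match")
})

test_that("duplicate gene rows collapse to the highest-mean row", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "A\t1\t1", "a\t10\t10", "B\t2\t2"), p)
  M <- load_expression(p)
  expect_equal(dim(M)[1], 2L)
  expect_equal(unname(M$values["A", 1]), 10)
})

test_that("drop_zero_genes removes exactly the all-zero rows", {
  v <- matrix(1, 10, 4)
  v[c(2, 5, 9), ] <- 0
  v[3, ] <- c(0, 0, 0.01, 0)   # one nonzero cell -> retained
  M <- drop_zero_genes(make_rpkm(v))
  expect_equal(dim(M)[1], 7L)
  expect_true("G03" %in% gene_ids(M))

  big <- matrix(runif(400), 100, 4)
  big[sample(100, 7), ] <- 0
  expect_equal(dim(drop_zero_genes(make_rpkm(big)))[1], 93L)

  expect_error(drop_zero_genes(make_rpkm(matrix(0, 3, 2))), "empty matrix")
})

test_that("log transform maps v to log2(v+1) once and only once", {
  M <- make_rpkm(matrix(c(0, 1, 3, 7), 2, 2))
  L <- log_transform(M)
  expect_equal(unname(as.vector(L$values)), c(0, 1, 2, 3))
  expect_equal(L$unit_state, "LOG2_RPKM_PLUS1")
  expect_error(log_transform(L), "already log-transformed")
  # monotone within a gene: ranking of cells preserved
  set.seed(9)
  v <- matrix(rexp(50), 5, 10)
  L2 <- log_transform(make_rpkm(v))
  for (g in 1:5) expect_equal(order(L2$values[g, ]), order(v[g, ]))
})

test_that("0.3-RPKM mean filter keeps the boundary and matches a naive mean", {
  v <- rbind(matrix(0.2, 1, 5), matrix(0.3, 1, 5), matrix(2, 1, 5))
  M <- filter_low_expression(make_rpkm(v))
  expect_setequal(gene_ids(M), c("G02", "G03"))

  set.seed(21)
  # 20 genes, exactly 5 with mean < 0.3 by construction
  means <- c(runif(5, 0.01, 0.29), runif(15, 0.35, 30))
  v <- matrix(NA_real_, 20, 40)
  for (g in 1:20) { row <- rexp(40); v[g, ] <- row * means[g] / mean(row) }
  M <- make_rpkm(v)
  kept <- filter_low_expression(M)
  naive_keep <- sapply(1:20, function(g) sum(v[g, ]) / 40 >= 0.3)
  expect_equal(dim(kept)[1], 15L)
  expect_setequal(gene_ids(kept), gene_ids(M)[naive_keep])

  # filter applies on the RPKM-scale means even after the log transform
  kept_log <- filter_low_expression(log_transform(M))
  expect_setequal(gene_ids(kept_log), gene_ids(kept))

  # idempotence
  expect_equal(filter_low_expression(kept)$values, kept$values)
})

test_that("subset_to_annotation keeps the intersection and errors on none", {
  M <- make_rpkm(matrix(1:12, 3, 4), genes = c("A", "B", "C"))
  ann <- build_annotation(list(gene_set("ASD", c("B", "C", "D"))))
  sub <- subset_to_annotation(M, ann)
  expect_setequal(gene_ids(sub), c("B", "C"))

  full <- subset_to_annotation(M, build_annotation(list(gene_set("X", c("A", "B", "C")))))
  expect_equal(full$values, M$values)

  expect_error(subset_to_annotation(M, build_annotation(list(gene_set("X", "Z")))),
               "no annotated gene")
})

test_that("preprocessing is invariant to gene-row permutation", {
  set.seed(33)
  v <- matrix(rexp(200, 2), 20, 10)
  v[3, ] <- 0
  M1 <- filter_low_expression(log_transform(drop_zero_genes(make_rpkm(v))))
  perm <- sample(20)
  M2 <- filter_low_expression(log_transform(drop_zero_genes(
    make_rpkm(v[perm, ], genes = sprintf("G%02d", perm)))))
  common <- gene_ids(M1)
  expect_setequal(common, gene_ids(M2))
  expect_equal(M1$values[common, ], M2$values[common, ])
})

test_that("sample outlier flagging finds a globally shifted sample", {
  set.seed(7)
  v <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(sprintf("G%02d", 1:50), sprintf("S%02d", 1:20)))
  v[, 13] <- v[, 13] + 10
  M <- expr_matrix(v - min(v), "RPKM")
  M$unit_state <- "LOG2_RPKM_PLUS1"
  flagged <- sample_outlier_report(M)
  expect_equal(flagged, colnames(M$values)[13])

  # identical samples: nothing to flag
  same <- matrix(rep(1:10, 5), 10, 5,
                 dimnames = list(sprintf("G%02d", 1:10), sprintf("S%02d", 1:5)))
  Ms <- expr_matrix(same, "RPKM"); Ms$unit_state <- "LOG2_RPKM_PLUS1"
  expect_length(sample_outlier_report(Ms), 0L)

  # two samples: warning and empty report
  two <- Ms; two$values <- two$values[, 1:2]
  expect_warning(res <- sample_outlier_report(two), ">= 3 samples")
  expect_length(res, 0L)
})

test_that("QC statistics report means and the filter verdict", {
  v <- rbind(matrix(0.1, 1, 4), matrix(3, 1, 4))
  qc <- qc_statistics(make_rpkm(v))
  expect_equal(qc$kept, c(0L, 1L))
  expect_equal(qc$mean_rpkm, c(0.1, 3))
  expect_match(qc$reason[1], "mean_rpkm")
})
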