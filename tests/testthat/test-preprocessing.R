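test_that("gene filtering removes high-zero genes and preserves order", {
  # 3 genes with zero proportions 0.5, 0.99, 1.0 across 1000 cells
  counts <- rbind(
    c(rep(1L, 500), rep(0L, 500)),
    c(rep(1L, 10), rep(0L, 990)),
    rep(0L, 1000)
  )
  expect_identical(filter_genes(counts, 0.99), c(1L, 2L))

  # a gene with 995/1000 zeros exceeds the 99% default and is removed
  counts2 <- rbind(c(rep(1L, 5), rep(0L, 995)), rep(1L, 1000))
  expect_identical(filter_genes(counts2), 2L)

  # a gene with no zeros is always retained
  expect_true(1L %in% filter_genes(matrix(1L, 1, 10), 0.01))

  expect_error(filter_genes(matrix(integer(0), 0, 0)), "non-empty")
  expect_error(filter_genes(matrix(0L, 2, 10), 0.5), "0.5")
})

test_that("gene filtering is idempotent and monotone in the threshold", {
  set.seed(3)
  counts <- matrix(rpois(50 * 40, rep(c(0.05, 0.5, 2, 8), each = 10)), 50, 40)
  for (th in c(0.5, 0.8, 0.95)) {
    keep <- filter_genes(counts, th)
    expect_identical(filter_genes(counts[keep, , drop = FALSE], th),
                     seq_along(keep))
  }
  k1 <- filter_genes(counts, 0.95)
  k2 <- filter_genes(counts, 0.8)
  k3 <- filter_genes(counts, 0.5)
  expect_true(all(k2 %in% k1))
  expect_true(all(k3 %in% k2))
})

test_that("log normalization matches the stated formula", {
  # counts (2, 3) in one cell, scale 10: log(1 + 10*2/5), log(1 + 10*3/5)
  m <- matrix(c(2, 3), 2, 1)
  expect_equal(log_normalize(m, 10), matrix(c(log(5), log(7)), 2, 1))

  # zero entry maps to 0; colsum 10, scale 1e4 -> log(1 + 1e4)
  m2 <- matrix(c(0, 10), 2, 1)
  expect_equal(log_normalize(m2, 1e4),
               matrix(c(0, log(10001)), 2, 1))

  # uniform counts: every entry log(1 + scale / n_genes)
  m3 <- matrix(7, 5, 3)
  expect_true(all(abs(log_normalize(m3, 100) - log(1 + 100 / 5)) < 1e-12))

  expect_error(log_normalize(matrix(c(-1, 2), 2, 1)), "nonnegative")
  expect_error(log_normalize(matrix(c(0, 0, 1, 2), 2, 2)), "zero total")
})

test_that("log normalization preserves within-cell rank order", {
  set.seed(4)
  counts <- matrix(rpois(30 * 8, 5), 30, 8)
  counts[1, ] <- 0:7 * 10
  expr <- log_normalize(counts)
  for (i in seq_len(ncol(counts)))
    expect_identical(order(expr[, i]), order(counts[, i]))
})

test_that("bundle construction maps time labels and validates nesting", {
  counts <- matrix(rpois(5 * 12, 10), 5, 12)
  b <- expression_bundle(counts, time = rep(c("D0", "D3", "D1"), each = 4),
                         sample_id = rep(1:3, each = 4))
  # character labels keep first-appearance order
  expect_identical(b$time_map$label, c("D0", "D3", "D1"))
  expect_identical(unique(b$time), 1:3)

  bn <- expression_bundle(counts, time = rep(c(10, 2, 5), each = 4),
                          sample_id = rep(1:3, each = 4))
  expect_identical(bn$time_map$label, c(2, 5, 10))  # numeric sorted ascending

  expect_error(expression_bundle(counts, time = rep(1:3, 4),
                                 sample_id = rep(1:3, each = 4)),
               "exactly one time point")
  expect_error(expression_bundle(counts, time = rep(1:2, each = 6),
                                 sample_id = rep(1:2, each = 6)),
               "3 time points")
})

test_that("pre-normalized expression is accepted unchanged", {
  expr <- matrix(rnorm(4 * 9), 4, 9)
  b <- expression_bundle(expr = expr, time = rep(1:3, each = 3),
                         sample_id = rep(1:3, each = 3))
  expect_identical(b$expr, expr)
  expect_null(b$counts)
})

test_that("stage down-sampling caps cells, is reproducible, keeps labels", {
  counts <- matrix(rpois(3 * 300, 5) + 1L, 3, 300)
  b <- expression_bundle(counts, time = rep(1:3, c(150, 100, 50)),
                         sample_id = rep(1:3, c(150, 100, 50)),
                         max_zero_prop = NULL)
  d <- downsample_stage(b, 80, seed = 9)
  expect_identical(as.integer(table(d$time)), c(80L, 80L, 50L))
  d2 <- downsample_stage(b, 80, seed = 9)
  expect_identical(d$cell_names, d2$cell_names)
  # each retained cell keeps its original sample/time pairing
  ix <- match(d$cell_names, b$cell_names)
  expect_identical(d$time, b$time[ix])
  expect_identical(as.character(d$sample_id), as.character(b$sample_id[ix]))
})

test_that("time permutation shuffles whole samples and preserves the label multiset", {
  b <- gaussian_bundle(G = 3, T_n = 4, samples_per_t = 2, cells = 5, seed = 2)
  pb <- permute_times(b, seed = 5)
  expect_identical(sort(as.integer(tapply(pb$time, pb$sample_id, unique))),
                   sort(as.integer(tapply(b$time, b$sample_id, unique))))
  # cells within a sample share one permuted label
  expect_true(all(tapply(pb$time, pb$sample_id,
                         function(z) length(unique(z))) == 1L))
  expect_identical(permute_times(b, seed = 5)$time, pb$time)
})

test_that("matrix and metadata readers round-trip a bundle", {
  td <- withr::local_tempdir()
  counts <- toy_counts()
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(td, "m.mtx"))
  writeLines(rownames(counts), file.path(td, "genes.tsv"))
  writeLines(colnames(counts), file.path(td, "barcodes.tsv"))
  m <- read_counts_mtx(file.path(td, "m.mtx"), file.path(td, "genes.tsv"),
                       file.path(td, "barcodes.tsv"))
  expect_equal(as.matrix(m), counts, ignore_attr = TRUE)
  expect_identical(dimnames(m), dimnames(counts))

  write.csv(as.data.frame(counts), file.path(td, "dense.csv"))
  dm <- read_counts_dense(file.path(td, "dense.csv"))
  expect_equal(dm, counts, ignore_attr = TRUE)

  md <- data.frame(cell = colnames(counts), time = c(1, 1, 2, 3),
                   sample = c("a", "a", "b", "c"))
  write.csv(md, file.path(td, "meta.csv"), row.names = FALSE)
  b <- bundle_from_files(file.path(td, "dense.csv"), file.path(td, "meta.csv"),
                         max_zero_prop = NULL)
  expect_s3_class(b, "expr_bundle")
  expect_identical(ncol(b$expr), 4L)
  expect_error(read_cell_metadata(file.path(td, "dense.csv")),
               "must contain columns")
})
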