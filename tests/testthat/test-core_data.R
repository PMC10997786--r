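test_that("MTX round-trip preserves counts exactly and rejects bad inputs", {
  m <- tiny_aem(seed = 3)
  dir <- withr::local_tempdir()
  write_expression_matrix(m, dir)
  back <- read_expression_matrix(file.path(dir, "matrix.mtx"),
                                 file.path(dir, "features.tsv"),
                                 file.path(dir, "barcodes.tsv"),
                                 file.path(dir, "cell_meta.tsv"))
  expect_identical(as.matrix(back$counts), as.matrix(m$counts))
  expect_identical(back$gene_ids, m$gene_ids)
  expect_identical(back$cell_meta$cell_id, m$cell_meta$cell_id)

  # 3x2 toy matrix, then metadata missing one barcode
  toy <- Matrix::Matrix(matrix(c(1, 0, 2, 0, 3, 4), nrow = 3), sparse = TRUE)
  dir2 <- withr::local_tempdir()
  Matrix::writeMM(Matrix::t(toy), file.path(dir2, "matrix.mtx"))
  writeLines(c("gA", "gB"), file.path(dir2, "features.tsv"))
  writeLines(c("c1", "c2", "c3"), file.path(dir2, "barcodes.tsv"))
  meta <- data.frame(cell_id = c("c1", "c2", "c3"), sample_id = "s1",
                     patient_id = "p1", day = 3, cell_type = "T",
                     severity = "mild")
  write.table(meta, file.path(dir2, "cell_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  got <- read_expression_matrix(file.path(dir2, "matrix.mtx"),
                                file.path(dir2, "features.tsv"),
                                file.path(dir2, "barcodes.tsv"),
                                file.path(dir2, "cell_meta.tsv"))
  expect_equal(dim(got), c(3L, 2L))
  write.table(meta[-2, ], file.path(dir2, "cell_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(
    read_expression_matrix(file.path(dir2, "matrix.mtx"),
                           file.path(dir2, "features.tsv"),
                           file.path(dir2, "barcodes.tsv"),
                           file.path(dir2, "cell_meta.tsv")),
    "c2")
  # dimension mismatch names the offending file
  writeLines(c("gA", "gB", "gC"), file.path(dir2, "features.tsv"))
  expect_error(
    read_expression_matrix(file.path(dir2, "matrix.mtx"),
                           file.path(dir2, "features.tsv"),
                           file.path(dir2, "barcodes.tsv"),
                           file.path(dir2, "cell_meta.tsv")),
    "features.tsv")
})

test_that("aem constructor enforces its invariants", {
  meta <- data.frame(cell_id = c("c1", "c2"), sample_id = "s", patient_id = "p",
                     day = 3, cell_type = "T", severity = "mild")
  counts <- matrix(c(1, 2, 0, 5), 2)
  expect_s3_class(aem(counts, meta, c("g1", "g2")), "aem")
  expect_error(aem(-counts, meta, c("g1", "g2")), "non-negative")
  expect_error(aem(counts + 0.5, meta, c("g1", "g2")), "integral")
  expect_error(aem(counts, meta, c("g1", "g1")), "duplicate")
  meta_bad <- meta; meta_bad$day <- 4
  expect_error(aem(counts, meta_bad, c("g1", "g2")), "time grid")
  meta_ctrl <- meta; meta_ctrl$day <- NA; meta_ctrl$severity <- "control"
  expect_s3_class(aem(counts, meta_ctrl, c("g1", "g2")), "aem")
})

test_that("normalize_counts matches the closed-form formula", {
  counts <- rbind(c(100, 900), c(5, 5))
  norm <- normalize_counts(counts, scale_factor = 1e4)
  # count 100 of total 1000 at sf 10000 -> ln(1 + 1000)
  expect_equal(norm[1, 1], log(1 + 1000), tolerance = 1e-12)
  expect_equal(norm[1, 2], log(1 + 9000), tolerance = 1e-12)
  expect_equal(norm[2, 1], log(1 + 5 / 10 * 1e4), tolerance = 1e-12)

  # zero-total cell identified by name
  counts2 <- rbind(c(0, 0), c(1, 2))
  rownames(counts2) <- c("bad_cell", "ok")
  expect_error(normalize_counts(counts2), "bad_cell")

  # all-zero gene stays all zero
  counts3 <- cbind(c(3, 1), c(0, 0))
  expect_true(all(normalize_counts(counts3)[, 2] == 0))
})

test_that("normalize_counts commutes with gene permutation", {
  set.seed(42)
  counts <- matrix(rpois(60, 3), nrow = 6)
  counts[1, ] <- counts[1, ] + 1  # no zero-total rows
  perm <- sample(ncol(counts))
  a <- normalize_counts(counts[, perm])
  b <- normalize_counts(counts)[, perm]
  expect_equal(as.matrix(a), as.matrix(b), tolerance = 1e-14)
})

test_that("select_hvgs ranks by the binned dispersion statistic", {
  m <- tiny_aem(seed = 5)
  expect_error(select_hvgs(m, ncol(m$counts) + 1), "exceeds")
  expect_setequal(select_hvgs(m, ncol(m$counts)), seq_len(ncol(m$counts)))

  # two genes, one constant, one varying
  meta <- data.frame(cell_id = paste0("c", 1:4), sample_id = "s",
                     patient_id = "p", day = 3, cell_type = "T",
                     severity = "mild")
  x <- aem(cbind(c(5, 5, 5, 5), c(1, 9, 1, 9)), meta, c("flat", "vary"))
  expect_identical(x$gene_ids[select_hvgs(x, 1)], "vary")

  # ranking equals a brute-force recomputation of the statistic
  norm <- as.matrix(m$normalized)
  v <- apply(norm, 2, var)
  mu <- colMeans(norm)
  bins <- cut(rank(mu, ties.method = "first"), breaks = 20, labels = FALSE)
  z <- numeric(length(v))
  for (b in unique(bins)) {
    i <- bins == b
    s <- sd(v[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (v[i] - mean(v[i])) / s
  }
  expected <- order(-z, m$gene_ids)[1:50]
  expect_identical(select_hvgs(m, 50), expected)
})

test_that("compute_embedding separates planted clusters and is deterministic", {
  set.seed(7)
  n <- 60
  counts <- matrix(rpois(2 * n * 40, 2), nrow = 2 * n)
  counts[1:n, 1:10] <- counts[1:n, 1:10] + rpois(n * 10, 25)
  counts[(n + 1):(2 * n), 11:20] <- counts[(n + 1):(2 * n), 11:20] + rpois(n * 10, 25)
  meta <- data.frame(cell_id = sprintf("c%03d", 1:(2 * n)), sample_id = "s",
                     patient_id = "p", day = 3, cell_type = "T",
                     severity = "mild")
  x <- aem(counts, meta, sprintf("g%02d", 1:40))
  emb <- compute_embedding(x, n_components = 5)
  labels <- rep(c("a", "b"), each = n)
  expect_gt(mean_silhouette(emb[, 1, drop = FALSE], labels), 0.5)
  expect_identical(emb, compute_embedding(x, n_components = 5))
  # single cell is degenerate
  expect_error(compute_embedding(subset_cells(x, 1)), "2 cells")
})

test_that("embedding maps duplicate cells to identical rows and orders variance", {
  m <- tiny_aem(seed = 9)
  dup <- subset_cells(m, c(1:30, 1))  # last row duplicates the first
  dup$cell_meta$cell_id[31] <- "dup"
  emb <- compute_embedding(dup, n_components = 5)
  expect_equal(unname(emb[31, ]), unname(emb[1, ]), tolerance = 1e-10)
  v <- apply(compute_embedding(m, n_components = 10), 2, var)
  expect_true(all(diff(v) <= 1e-10))
})
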