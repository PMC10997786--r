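test_that("target_metacell_count applies the round-to-10 rule with floor and overrides", {
  expect_identical(target_metacell_count(750), 10L)
  expect_identical(target_metacell_count(2480), 30L)
  expect_identical(target_metacell_count(120), 10L)
  expect_identical(target_metacell_count(3500), 50L)   # half rounds up
  expect_identical(target_metacell_count(5000, day = 28,
                                         day_overrides = list("28" = 20)), 20L)
  expect_identical(target_metacell_count(5000, day = 13,
                                         day_overrides = list("28" = 20)), 70L)
})

test_that("build_knn_graph matches a brute-force neighbour oracle", {
  set.seed(2)
  emb <- matrix(rnorm(80 * 3), ncol = 3)
  k <- 6
  adj <- build_knn_graph(emb, k)
  expect_true(Matrix::isSymmetric(adj))
  expect_true(all(Matrix::diag(adj) == 1))
  d <- as.matrix(dist(emb))
  for (i in c(1, 17, 80)) {
    nn <- order(d[i, ])[2:(k + 1)]
    sigma_i <- d[i, nn[ceiling(k / 3)]]
    for (j in nn) {
      nnj <- order(d[j, ])[2:(k + 1)]
      sigma_j <- d[j, nnj[ceiling(k / 3)]]
      expect_equal(adj[i, j], exp(-d[i, j]^2 / (sigma_i * sigma_j)),
                   tolerance = 1e-12)
    }
  }
  expect_error(build_knn_graph(emb, 0), "positive")
})

test_that("knn graph degenerate geometries", {
  # three equidistant points: all off-diagonal weights equal
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  adj <- build_knn_graph(tri, 2)
  off <- adj[upper.tri(adj)]
  expect_equal(off, rep(off[1], 3), tolerance = 1e-12)
  # duplicated cell gets weight 1 with its twin
  emb <- rbind(c(0, 0), c(0, 0), c(5, 5), c(9, 1))
  adj2 <- build_knn_graph(emb, 2)
  expect_equal(adj2[1, 2], 1)
})

test_that("sMetacells partition each day's cells and are deterministic", {
  m <- tiny_aem(seed = 71)
  emb <- compute_embedding(m, select_hvgs(m, 150), 15)
  smc <- construct_smetacells(m, emb, k = 10, seed = 1)
  for (day in unique(smc$meta$day)) {
    members <- unlist(smc$members[smc$meta$day == day])
    day_cells <- m$cell_meta$cell_id[m$cell_meta$day == day]
    expect_identical(sort(members), sort(day_cells))  # disjoint + cover
  }
  smc2 <- construct_smetacells(m, emb, k = 10, seed = 1)
  expect_identical(smc$meta, smc2$meta)
  expect_identical(smc$members, smc2$members)
  # purity/type fields are consistent with members
  for (i in seq_len(nrow(smc$meta))) {
    tys <- m$cell_meta$cell_type[match(smc$members[[i]], m$cell_meta$cell_id)]
    tp <- assign_type_and_purity(tys)
    expect_identical(smc$meta$cell_type[i], tp$cell_type)
    expect_equal(smc$meta$purity[i], tp$purity)
  }
})

test_that("singleton request yields one metacell per cell with purity 1", {
  m <- tiny_aem(seed = 73)
  sub <- subset_cells(m, which(m$cell_meta$day == 3)[1:25])
  emb <- compute_embedding(sub, n_components = 5)
  smc <- construct_smetacells(sub, emb, n_metacells = 25, k = 5)
  expect_equal(nrow(smc$meta), 25)
  expect_true(all(smc$meta$n_members == 1))
  expect_true(all(smc$meta$purity == 1))
  expect_error(construct_smetacells(sub, emb, n_metacells = 26, k = 5),
               "exceeds")
})

test_that("two well-separated planted clusters are recovered exactly", {
  set.seed(5)
  n <- 40
  counts <- matrix(rpois(2 * n * 30, 2), nrow = 2 * n)
  counts[1:n, 1:8] <- counts[1:n, 1:8] + rpois(n * 8, 40)
  counts[(n + 1):(2 * n), 9:16] <- counts[(n + 1):(2 * n), 9:16] + rpois(n * 8, 40)
  meta <- data.frame(cell_id = sprintf("c%03d", 1:(2 * n)), sample_id = "s",
                     patient_id = "p", day = 3,
                     cell_type = rep(c("A", "B"), each = n), severity = "mild")
  x <- aem(counts, meta, sprintf("g%02d", 1:30))
  emb <- compute_embedding(x, n_components = 3)
  smc <- construct_smetacells(x, emb, n_metacells = 2, k = 10)
  expect_equal(nrow(smc$meta), 2)
  expect_setequal(smc$meta$cell_type, c("A", "B"))
  expect_true(all(smc$meta$purity == 1))
  expect_true(all(smc$meta$n_members == n))
})

test_that("rMetacells average 20 same-type cells, purity 1, strata skipped", {
  m <- tiny_aem(seed = 75)
  rmc <- construct_rmetacells(m, n_per_metacell = 20, n_replicates = 3, seed = 9)
  expect_true(all(rmc$meta$purity == 1))
  expect_true(all(rmc$meta$n_members == 20))
  # stratum of exactly n cells: expression equals the stratum mean
  sub <- subset_cells(m, which(m$cell_meta$day == 3 &
                               m$cell_meta$cell_type == "type1")[1:20])
  one <- construct_rmetacells(sub, 20, 1, seed = 1)
  expect_equal(unname(one$expression[1, ]),
               unname(Matrix::colMeans(sub$normalized)), tolerance = 1e-12)
  # stratum of 19 cells is skipped with a warning
  sub19 <- subset_cells(m, which(m$cell_meta$day == 3 &
                                 m$cell_meta$cell_type == "type1")[1:19])
  expect_error(expect_warning(construct_rmetacells(sub19, 20, 1, seed = 1),
                              "skipped"))
  expect_error(construct_rmetacells(m, 20, 3), "seed")
})

test_that("rMetacell means are unbiased for the stratum mean across seeds", {
  m <- tiny_aem(seed = 77)
  sub <- subset_cells(m, which(m$cell_meta$day == 7 &
                               m$cell_meta$cell_type == "type2"))
  stratum_mean <- Matrix::colMeans(sub$normalized)
  devs <- sapply(1:40, function(s) {
    rmc <- construct_rmetacells(sub, 20, 1, seed = s)
    mean(rmc$expression[1, ] - stratum_mean)
  })
  expect_lt(abs(mean(devs)), 3 * sd(devs) / sqrt(length(devs)) + 1e-4)
})

test_that("pseudobulk matches the hand formula and conserves cells", {
  meta <- data.frame(cell_id = c("c1", "c2"), sample_id = "s1",
                     patient_id = "p1", day = 3, cell_type = "T",
                     severity = "mild")
  x <- aem(rbind(c(1, 0), c(1, 2)), meta, c("g1", "g2"))
  pb <- aggregate_pseudobulk(x)
  sums <- c(2, 2); tot <- 4
  expect_equal(unname(pb$expression[1, ]), log1p(sums / tot * 1e4),
               tolerance = 1e-12)
  # one cell in a stratum equals that cell renormalized
  x1 <- subset_cells(x, 1)
  pb1 <- aggregate_pseudobulk(x1)
  expect_equal(unname(pb1$expression[1, ]), log1p(c(1, 0) / 1 * 1e4),
               tolerance = 1e-12)
  # conservation over a full simulation
  m <- tiny_aem(seed = 79)
  pbm <- aggregate_pseudobulk(m)
  expect_equal(sum(pbm$meta$n_members), nrow(m$counts))
})

test_that("assign_type_and_purity handles majorities and ties", {
  got <- assign_type_and_purity(c(rep("plasma", 18), "NK", "T"))
  expect_identical(got$cell_type, "plasma")
  expect_equal(got$purity, 0.90)
  expect_equal(assign_type_and_purity(rep("NK", 7))$purity, 1.0)
  tie <- assign_type_and_purity(rep(c("A", "B"), each = 10))
  expect_identical(tie$cell_type, "A")
  expect_equal(tie$purity, 0.5)
  expect_error(assign_type_and_purity(character(0)), "member")
})

test_that("filter_for_analysis applies cell-count, purity and day masks", {
  m <- tiny_aem(seed = 81)
  rmc <- construct_rmetacells(m, 20, 3, seed = 3)
  # type totals here are 3 reps x 20 cells x 10 days = 600 per type
  expect_identical(filter_for_analysis(rmc, 600)$meta, rmc$meta)
  expect_error(filter_for_analysis(rmc, 601), "removed all")
  masked <- filter_for_analysis(rmc, 0, day_masks = list(type1 = c(3, 7, 9)))
  expect_true(all(!(masked$meta$cell_type == "type1" &
                    masked$meta$day %in% c(3, 7, 9))))
  expect_true(any(masked$meta$cell_type == "type2" & masked$meta$day == 3))
  # purity threshold
  rmc$meta$purity <- rep(c(0.96, 0.90), length.out = nrow(rmc$meta))
  pure <- filter_for_analysis(rmc, 0, purity_min = 0.95)
  expect_true(all(pure$meta$purity > 0.95))
  # identity when nothing filters
  expect_identical(filter_for_analysis(rmc, 0)$meta, rmc$meta)
})
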