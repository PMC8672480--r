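test_that("batch allocation covers individuals and creates the right replicates", {
  ids <- sprintf("i%d", 1:5)
  # 2 batches of 3 over 5 individuals: 6 slots -> exactly 1 replicate
  d <- design_params(n_individuals = 5L, batch_n_cells = c(30L, 30L),
                     batch_size = 3L)
  cd <- build_design(d, ids, seed = 1)
  members <- cd$batch_members
  expect_true(all(lengths(members) == 3L))
  expect_identical(length(intersect(members[[1]], members[[2]])), 1L)
  expect_setequal(union(members[[1]], members[[2]]), ids)
  expect_true(all(table(cd$cells$batch) == 30L))
  # one batch holding everyone: no replicates
  d1 <- design_params(n_individuals = 5L, batch_n_cells = 50L,
                      batch_size = 5L)
  cd1 <- build_design(d1, ids, seed = 2)
  expect_identical(sort(cd1$batch_members[[1]]), sort(ids))
  # cells split evenly across a batch's individuals
  expect_true(all(table(cd1$cells$individual) == 10L))
  expect_error(build_design(design_params(n_individuals = 5L,
                                          batch_size = 5L),
                            ids[1:3], seed = 1), "batch_size")
})

test_that("conditions are apportioned by largest remainder", {
  ids <- sprintf("i%d", 1:6)
  d <- design_params(n_individuals = 6L, condition_probs = c(0.5, 0.5))
  cd <- build_design(d, ids, seed = 3)
  expect_equal(as.vector(table(cd$individuals$condition)), c(3L, 3L))
  # cells inherit their individual's condition
  m <- merge(cd$cells, cd$individuals, by = "individual")
  expect_true(all(m$condition.x == m$condition.y))
})

test_that("batch factors are bidirectional log-normals", {
  f0 <- sample_batch_factors(1000, batch_loc = 0, batch_scale = 0,
                             seed = 4)
  expect_true(all(f0 == 1))
  # scale 0, loc 0.1: factors are exactly e^0.1 or e^-0.1, about half each
  f1 <- sample_batch_factors(10000, batch_loc = 0.1, batch_scale = 0,
                             seed = 5)
  expect_true(all(abs(log(f1)) - 0.1 < 1e-12))
  frac_up <- mean(f1 > 1)
  expect_lt(abs(frac_up - 0.5), 3 * sqrt(0.25 / 10000))
  # a larger-scale batch shows larger typical |log factor|
  f2 <- sample_batch_factors(5000, batch_loc = c(0.05, 0.05),
                             batch_scale = c(0.05, 0.5), seed = 6)
  expect_gt(mean(abs(log(f2[, 2]))), mean(abs(log(f2[, 1]))))
})

test_that("library sizes follow the log-normal model", {
  sc <- sc_params(lib_loc = 8, lib_scale = 0)
  expect_true(all(sample_library_sizes(100, sc, seed = 7) == exp(8)))
  sc2 <- sc_params(lib_loc = 8, lib_scale = 0.4)
  L <- sample_library_sizes(100000, sc2, seed = 8)
  expect_lt(abs(median(L) - exp(8)) / exp(8), 0.02)
  expect_identical(sample_library_sizes(10, sc2, seed = 9),
                   sample_library_sizes(10, sc2, seed = 9))
})

test_that("cell means combine slices, batch factors and library scaling", {
  base <- matrix(c(1, 2, 3, 4), 2, 2,
                 dimnames = list(c("g1", "g2"), c("iA", "iB")))
  pm <- pop_means(base, gene_ids = c("g1", "g2"),
                  individual_ids = c("iA", "iB"))
  cells <- data.frame(cell_id = c("c1", "c2", "c3"),
                      individual = c("iA", "iA", "iB"),
                      batch = "batch1", group = "group1")
  bf <- matrix(1, 2, 1, dimnames = list(NULL, "batch1"))
  L <- c(100, 50, 80)
  mu <- compute_cell_means(pm, cells, bf, L)
  expect_equal(colSums(mu), c(c1 = 100, c2 = 50, c3 = 80))
  # proportional to the individual's popmeans column
  expect_equal(unname(mu[, 1]),
               unname(base[, 1] / sum(base[, 1]) * 100))
  # scale invariance: doubling an individual's means leaves mu unchanged
  pm2 <- pop_means(base * c(1, 1, 2, 2), gene_ids = c("g1", "g2"),
                   individual_ids = c("iA", "iB"))
  mu2 <- compute_cell_means(pm2, cells, bf, L)
  expect_equal(mu[, 3], mu2[, 3])
  expect_error(compute_cell_means(pop_means(base * 0 + c(0, 0, 1, 1),
                                            gene_ids = c("g1", "g2"),
                                            individual_ids = c("iA", "iB")),
                                  cells, bf, L), "zero total")
})

test_that("count sampling is mean-preserving with BCV over-dispersion", {
  sc <- sc_params(bcv_common = 0.3, bcv_df = 20)
  mu <- matrix(rep(c(0, 2, 50), each = 30000), 3, byrow = TRUE)
  cnt <- sample_counts(mu, sc, seed = 10)
  expect_true(all(cnt[1, ] == 0)) # zero mean -> zero counts
  expect_lt(abs(mean(cnt[2, ]) - 2) / 2, 0.05)
  expect_lt(abs(mean(cnt[3, ]) - 50) / 50, 0.05)
  # over-dispersed relative to Poisson
  expect_gt(var(cnt[3, ]) / mean(cnt[3, ]), 2)
  # with bcv_common 0 and df -> Inf the dispersion B = 1/sqrt(mu), so
  # var = mu(1 + mu B^2) = 2 mu exactly: the gamma layer always
  # contributes one extra unit of mean-scaled variance
  sc0 <- sc_params(bcv_common = 0, bcv_df = Inf)
  cnt0 <- sample_counts(mu, sc0, seed = 11)
  expect_lt(abs(var(cnt0[3, ]) / mean(cnt0[3, ]) - 2), 0.15)
})

test_that("dropout thins counts by the logistic keep rule", {
  sc_off <- sc_params(dropout_enabled = FALSE)
  cnt <- matrix(5L, 10, 10)
  mu <- matrix(2, 10, 10)
  expect_identical(apply_dropout(cnt, mu, sc_off, seed = 12), cnt)
  # midpoint far below every log-mean: nothing is dropped
  sc_lo <- sc_params(dropout_enabled = TRUE, dropout_mid = -1e3,
                     dropout_shape = -1)
  expect_identical(apply_dropout(cnt, mu, sc_lo, seed = 13),
                   cnt * matrix(1L, 10, 10))
  # midpoint at the log-mean: ~half of the entries zeroed
  sc_mid <- sc_params(dropout_enabled = TRUE, dropout_mid = log(2),
                      dropout_shape = -1)
  big <- matrix(5L, 100, 200)
  mug <- matrix(2, 100, 200)
  kept <- apply_dropout(big, mug, sc_mid, seed = 14)
  frac0 <- mean(kept == 0)
  expect_lt(abs(frac0 - 0.5), 3 * sqrt(0.25 / length(big)))
})

test_that("the full simulation is reproducible and isolates substreams", {
  p <- small_params(n_genes = 150L, n_ind = 5L, cells = 20L, seed = 31L)
  b1 <- simulate_population(p)
  b2 <- simulate_population(p)
  expect_identical(as.matrix(b1$counts), as.matrix(b2$counts))
  expect_identical(b1$key, b2$key)
  expect_identical(b1$cells, b2$cells)
  # changing only cell-level parameters leaves the key untouched but
  # changes the counts (shared-biology, different-chemistry design)
  p2 <- update_params(p, list(sc = list(lib_loc = 9, bcv_common = 0.3)))
  b3 <- simulate_population(p2)
  expect_identical(b1$key$genes, b3$key$genes)
  expect_identical(b1$key$baseline_means, b3$key$baseline_means)
  expect_false(identical(as.matrix(b1$counts), as.matrix(b3$counts)))
})
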