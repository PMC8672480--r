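test_that("base means follow the population gamma with outlier injection", {
  pop <- pop_params(mean_shape = 2, mean_rate = 1)
  # no outliers when out_prob = 0
  bm <- sample_base_means(pop, sc_params(out_prob = 0), 1000, seed = 1)
  expect_false(any(bm$outlier_flag))
  # gamma moments: mean 2, sd sqrt(2); 100,000 draws within 3 s.e.
  bm2 <- sample_base_means(pop, sc_params(out_prob = 0), 100000, seed = 2)
  se <- sqrt(2) / sqrt(100000)
  expect_lt(abs(mean(bm2$means) - 2), 3 * se)
  # forced factor 1: every mean replaced by the median
  bm3 <- sample_base_means(pop, sc_params(out_prob = 1, out_loc = 0,
                                          out_scale = 0), 50, seed = 3)
  expect_true(all(bm3$outlier_flag))
  expect_true(all(bm3$means == bm3$means[1]))
})

test_that("cv sampling follows the bin-specific gamma scaled by similarity", {
  pop <- pop_params(mean_shape = 2, mean_rate = 1, n_bins = 2L,
                    bin_edges = c(0, 2, Inf),
                    cv_shape_per_bin = c(4, 20),
                    cv_rate_per_bin = c(8, 100))
  lam <- c(rep(1, 10000), rep(5, 10000)) # bin 1 then bin 2
  cv <- sample_variances(lam, pop, seed = 4)
  ks1 <- suppressWarnings(ks.test(cv[1:10000], "pgamma", 4, 8))
  ks2 <- suppressWarnings(ks.test(cv[10001:20000], "pgamma", 20, 100))
  expect_gt(ks1$p.value, 0.01)
  expect_gt(ks2$p.value, 0.01)
  # the two bins really differ
  expect_lt(suppressWarnings(
    ks.test(cv[1:10000], cv[10001:20000])$p.value), 1e-10)
  # similarity scale multiplies the rate: s_v large -> cv tiny
  pop_s <- pop_params(mean_shape = 2, mean_rate = 1, n_bins = 2L,
                      bin_edges = c(0, 2, Inf),
                      cv_shape_per_bin = c(4, 20),
                      cv_rate_per_bin = c(8, 100),
                      similarity_scale = 1e6)
  expect_lt(max(sample_variances(lam, pop_s, seed = 4)), 1e-3)
})

test_that("individual means are normal draws with sd = mean * cv, floored at 0", {
  ids <- sprintf("i%05d", 1:10000)
  m <- sample_individual_means(c(a = 10), c(0.5), ids, seed = 5)
  expect_equal(dim(m), c(1L, 10000L))
  expect_lt(abs(sd(m[1, ]) - 5) / 5, 0.05)
  # sigma 0: exact copies
  m0 <- sample_individual_means(c(10, 3), c(0, 0), ids[1:4], seed = 6)
  expect_true(all(m0 == c(10, 3)))
  # heavy noise at a tiny mean never goes negative
  mneg <- sample_individual_means(c(0.1), c(50), ids, seed = 7)
  expect_true(all(mneg >= 0))
})

test_that("quantile normalization maps columns onto the target gamma", {
  sc <- sc_params(mean_shape = 0.6, mean_rate = 0.3)
  set.seed(8)
  x <- matrix(rlnorm(600 * 3, 2, 1), 600, 3)
  qn <- quantile_normalize(x, sc)
  for (j in 1:3) {
    ks <- suppressWarnings(ks.test(qn[, j], "pgamma", 0.6, 0.3))
    expect_gt(ks$p.value, 0.01)
    # monotone: rank order preserved within the column
    expect_true(all(diff(qn[order(x[, j]), j]) >= 0))
  }
  # a column already equal to those quantiles is a fixed point up to
  # permutation: re-normalizing returns the same set of values
  expect_equal(sort(quantile_normalize(qn, sc)[, 1]), sort(qn[, 1]))
})

test_that("eQTL effects follow lambda * (1 + G * beta) with specificity", {
  dos <- matrix(c(0, 1, 2), 1, 3,
                dimnames = list("s1", c("iA", "iB", "iC")))
  G <- genotype_matrix(dos, chrom = "chr1", pos = 50L)
  base <- matrix(10, 2, 3, dimnames = list(c("g1", "g2"),
                                           c("iA", "iB", "iC")))
  pm <- pop_means(base, gene_ids = c("g1", "g2"),
                  individual_ids = c("iA", "iB", "iC"),
                  groups = c("group1", "group2"),
                  conditions = c("condition1", "condition2", "condition1"))
  key <- data.frame(gene_id = "g1", snp_id = "s1", beta = 0.5,
                    specificity = "global",
                    coreg_partner = NA_character_)
  out <- apply_eqtl(pm, key, G)
  # hand-evaluated: 10, 10+10*1*0.5 = 15, 10+10*2*0.5 = 20, both slices
  expect_equal(unname(out$values["g1", , "group1"]), c(10, 15, 20))
  expect_equal(unname(out$values["g1", , "group2"]), c(10, 15, 20))
  expect_equal(unname(out$values["g2", , "group1"]), c(10, 10, 10))

  key$specificity <- "group:group2"
  out2 <- apply_eqtl(pm, key, G)
  expect_equal(unname(out2$values["g1", , "group1"]), c(10, 10, 10))
  expect_equal(unname(out2$values["g1", , "group2"]), c(10, 15, 20))

  key$specificity <- "condition:condition1"
  out3 <- apply_eqtl(pm, key, G)
  expect_equal(unname(out3$values["g1", , "group1"]), c(10, 10, 20))

  key$snp_id <- "missing_snp"
  expect_error(apply_eqtl(pm, key, G), "missing_snp")
})

test_that("DE factors hit the requested fraction and scale the right slices", {
  base <- matrix(5, 10000, 4)
  pm <- pop_means(base, groups = c("group1", "group2"),
                  conditions = rep("condition1", 4))
  # de_prob 0 -> identity
  r0 <- apply_de(pm, de_params(de_prob = 0), seed = 9)
  expect_equal(r0$pm$values, pm$values)
  expect_true(all(r0$de_factors == 1))
  # forced unit factors
  r1 <- apply_de(pm, de_params(de_prob = 1, de_loc = 0, de_scale = 0,
                               de_down_prob = 0), seed = 10)
  expect_true(all(r1$de_factors == 1))
  # binomial oracle on the DE fraction at de_prob 0.4
  r2 <- apply_de(pm, de_params(de_prob = 0.4), seed = 11)
  frac <- mean(r2$de_factors[, 2] != 1)
  expect_lt(abs(frac - 0.4), 3 * sqrt(0.4 * 0.6 / 10000))
  # factors recorded match the applied scaling
  expect_equal(r2$pm$values[, , 2], base * r2$de_factors[, 2],
               ignore_attr = TRUE)
})

test_that("condition DE multiplies the cohort's individuals across slices", {
  base <- matrix(5, 500, 6)
  pm <- pop_means(base, groups = "group1",
                  conditions = rep(c("condition1", "condition2"), each = 3))
  r <- apply_de(pm, de_params(cde_prob = 0.5), seed = 12)
  hit <- which(r$cde_factors[, "condition2"] != 1)
  expect_gt(length(hit), 100)
  g <- hit[1]
  expect_equal(unname(r$pm$values[g, 4:6, 1] / base[g, 4:6]),
               rep(r$cde_factors[g, "condition2"], 3))
})

test_that("replication mode uses the matrix directly and flags eQTL requests", {
  mat <- matrix(rgamma(200 * 4, 2, 0.1), 200, 4,
                dimnames = list(sprintf("g%03d", 1:200),
                                c("w", "x", "y", "z")))
  emp <- use_empirical_means(mat, bulk = FALSE)
  expect_error(use_empirical_means(mat - 100), "non-negative")
  p <- small_params(n_genes = 200L, n_ind = 4L, cells = 50L,
                    eqtl = list(eqtl_prob = 0))
  b <- simulate_population(p, empirical_means = emp)
  # ids propagate unchanged
  expect_identical(colnames(b$key$baseline_means), c("w", "x", "y", "z"))
  expect_identical(rownames(b$counts), rownames(mat))
  # baseline means are exactly the input (no QN for non-bulk input)
  expect_equal(unname(b$key$baseline_means), unname(mat))
  # requesting eQTL effects on top warns
  p2 <- small_params(n_genes = 200L, n_ind = 4L, cells = 10L,
                     eqtl = list(eqtl_prob = 0.5))
  expect_warning(simulate_population(p2, empirical_means = emp),
                 "compound")
})

test_that("replication mode reproduces the input expression pattern", {
  # low-noise regime: mean-aggregated counts correlate with the input
  set.seed(13)
  mat <- matrix(rgamma(100 * 4, 2, 0.05), 100, 4,
                dimnames = list(sprintf("g%03d", 1:100),
                                sprintf("i%d", 1:4)))
  p <- small_params(n_genes = 100L, n_ind = 4L, cells = 500L,
                    eqtl = list(eqtl_prob = 0),
                    sc = list(n_genes = 100L, bcv_common = 0.05,
                              bcv_df = Inf))
  b <- simulate_population(p, empirical_means = use_empirical_means(
    mat, bulk = FALSE))
  agg <- aggregate_counts(b$counts, b$cells$individual, method = "mean")
  r <- cor(as.vector(agg[, colnames(mat)]), as.vector(mat))
  expect_gt(r, 0.95)
})
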