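test_that("aggregation matches hand examples and a brute-force loop", {
  cnt <- matrix(c(2, 4, 0, 0), 2, 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), c("c1", "c2")))
  ind <- c("iA", "iA")
  expect_equal(unname(aggregate_counts(cnt, ind, "mean")[, 1]), c(3, 0))
  expect_equal(unname(aggregate_counts(cnt, ind, "sum")[, 1]), c(6, 0))
  # loop oracle on a random 50 x 200 matrix over 10 individuals
  set.seed(20)
  x <- matrix(rpois(50 * 200, 3), 50,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  ind2 <- sample(sprintf("i%02d", 1:10), 200, replace = TRUE)
  agg <- aggregate_counts(x, ind2, "mean")
  for (ii in unique(ind2)[c(1, 5, 10)]) {
    expect_equal(agg[, ii], rowMeans(x[, ind2 == ii, drop = FALSE]))
  }
  expect_error(aggregate_counts(x, ind2[-1], "mean"), "every cell")
})

test_that("variance explained matches a one-way ANOVA decomposition", {
  f <- rep(c("a", "b"), each = 20)
  # a gene equal to the factor indicator is fully explained
  x <- rbind(ind = as.numeric(f == "a"),
             noise = rnorm(40),
             const = rep(2, 40))
  ve <- variance_explained(x, f)
  expect_equal(unname(ve["ind"]), 100)
  expect_equal(unname(ve["const"]), 0) # constant gene -> 0 by convention
  # loop oracle via lm R^2 per gene
  set.seed(21)
  y <- matrix(rnorm(5 * 40), 5)
  ve2 <- variance_explained(y, f)
  for (g in 1:5) {
    r2 <- summary(lm(y[g, ] ~ f))$r.squared
    expect_equal(unname(ve2[g]), 100 * r2)
  }
  # independent gene, large n: near the (k-1)/(n-1) null expectation
  set.seed(22)
  big <- matrix(rnorm(2000), 1)
  f2 <- rep(c("a", "b"), 1000)
  expect_lt(variance_explained(big, f2), 1)
})

test_that("silhouette widths separate blobs and vanish under shuffling", {
  set.seed(23)
  blob <- cbind(matrix(rnorm(20 * 15, 0, 0.1), 20),
                matrix(rnorm(20 * 15, 10, 0.1), 20))
  lab <- rep(c("a", "b"), each = 15)
  w <- silhouette_widths(blob, lab)
  expect_true(all(w > 0.9))
  ws <- silhouette_widths(blob, sample(lab))
  expect_lt(abs(mean(ws)), 0.2)
  expect_error(silhouette_widths(blob, rep("a", 30)), "2 clusters")
  # brute-force oracle on 30 cells
  x <- matrix(rnorm(10 * 30), 10)
  lab2 <- rep(c("a", "b", "c"), each = 10)
  w2 <- silhouette_widths(x, lab2)
  d <- as.matrix(dist(t(x)))
  for (i in c(1, 15, 30)) {
    a <- mean(d[i, setdiff(which(lab2 == lab2[i]), i)])
    b <- min(sapply(setdiff(unique(lab2), lab2[i]),
                    function(l) mean(d[i, lab2 == l])))
    expect_equal(unname(w2[i]), (b - a) / max(a, b), tolerance = 1e-8)
  }
})

test_that("pseudobulk Wilcoxon DE controls the null and detects separation", {
  set.seed(24)
  cnt <- matrix(rpois(100 * 60, 5), 100,
                dimnames = list(sprintf("g%03d", 1:100), NULL))
  ind <- rep(sprintf("i%02d", 1:12), each = 5)
  cond <- setNames(rep(c("condition1", "condition2"), each = 6),
                   sprintf("i%02d", 1:12))
  de <- de_test_pseudobulk(cnt, ind, cond)
  # identical groups by construction: essentially nothing significant
  expect_lt(mean(de$q < 0.05), 0.02)
  # BH never shrinks the largest p
  expect_gte(de$q[which.max(de$p)], max(de$p))
  # a gene with disjoint, tie-free group supports reaches the exact
  # rank-sum minimum: two-sided p = 2 / choose(12, 6)
  cnt3 <- matrix(c(101:106, 1:6), 1,
                 dimnames = list("g1", NULL))
  de3 <- de_test_pseudobulk(cnt3, sprintf("i%02d", 1:12), cond)
  expect_equal(de3$p[1], 2 / choose(12, 6), tolerance = 1e-12)
  expect_error(de_test_pseudobulk(cnt, ind,
                                  setNames(c("a", rep("b", 11)),
                                           names(cond))),
               "at least 2 individuals")
})

test_that("the cis mapper recovers planted effects and controls the null", {
  set.seed(25)
  n_ind <- 200
  G <- simulate_genotypes(300, n_ind, maf_range = c(0.35, 0.45),
                          chrom_length = 1e6, seed = 26)
  ann <- gene_annotation(sprintf("g%02d", 1:20), rep("chr1", 20),
                         as.integer(seq(5e4, 9.5e5, length.out = 20)))
  # planted multiplicative effect lambda * (1 + G * omega), omega = 1
  esnp <- sapply(1:20, function(i)
    which(abs(G$pos - ann$pos[i]) <= 1e5)[1])
  lam <- rgamma(20, 2, 0.1)
  agg <- sapply(seq_len(n_ind), function(j)
    lam * (1 + G$dosage[esnp, j] * 1) *
      rlnorm(20, 0, 0.1))
  dimnames(agg) <- list(ann$gene_id, G$sample_ids)
  hits <- 0
  res <- map_eqtl_simple(agg, G, ann, window_bp = 1e5)
  expect_true(all(res$q < 0.05))
  expect_true(all(res$beta > 0))
  hits <- mean(res$snp_id == G$snp_ids[esnp])
  expect_gt(hits, 0.95)
  # noise-free linear relationship: slope recovered exactly
  g1 <- G$dosage[esnp[1], ]
  y <- 3 * g1 + 2
  agg1 <- matrix(y, 1, dimnames = list("g01", G$sample_ids))
  r1 <- map_eqtl_simple(agg1, G, ann[1, ], window_bp = 1e5)
  yt <- inverse_normal_transform(y)
  slope <- cov(yt, g1) / var(g1)
  expect_equal(r1$beta, slope, tolerance = 1e-10)
  expect_equal(r1$snp_id, G$snp_ids[esnp[1]])
})

test_that("the mapper's null is calibrated under permuted genotypes", {
  set.seed(27)
  G <- simulate_genotypes(200, 100, maf_range = c(0.1, 0.5),
                          chrom_length = 1e6, seed = 28)
  ann <- gene_annotation(sprintf("g%02d", 1:30), rep("chr1", 30),
                         as.integer(seq(5e4, 9.5e5, length.out = 30)))
  agg <- matrix(rgamma(30 * 100, 2, 0.1), 30,
                dimnames = list(ann$gene_id, G$sample_ids))
  res <- map_eqtl_simple(agg, G, ann, window_bp = 5e4)
  # expression independent of genotype: nothing survives BH at 5%
  expect_lt(mean(res$q < 0.05), 0.1)
})

test_that("confusion summaries implement the printed rate formulas", {
  truth <- setNames(c(rep(TRUE, 10), rep(FALSE, 10)),
                    sprintf("g%02d", 1:20))
  calls <- data.frame(gene_id = sprintf("g%02d", 1:20),
                      q = c(rep(0.01, 8), rep(0.5, 2),
                            rep(0.01, 2), rep(0.5, 8)))
  cs <- score_discoveries(truth, calls, 0.05)
  expect_identical(c(cs$TP, cs$FN, cs$FP, cs$TN), c(8L, 2L, 2L, 8L))
  expect_equal(cs$tpr, 0.8)
  expect_equal(cs$fdr, 0.2)
  # empty calls: rates reported as 0 with the undefined flag set
  none <- data.frame(gene_id = sprintf("g%02d", 1:20), q = 1)
  cs0 <- score_discoveries(truth, none, 0.05)
  expect_equal(cs0$fdr, 0)
  expect_true(cs0$undefined_fdr)
  # all-correct calls
  perfect <- data.frame(gene_id = sprintf("g%02d", 1:20),
                        q = c(rep(0.001, 10), rep(1, 10)))
  csp <- score_discoveries(truth, perfect, 0.05)
  expect_equal(csp$tpr, 1)
  expect_equal(csp$fdr, 0)
  expect_error(score_discoveries(truth,
                                 data.frame(gene_id = "zz", q = 0.5)),
               "absent")
})
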