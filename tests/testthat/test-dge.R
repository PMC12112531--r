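# Filtering, TMM, dispersion estimation, NB exact test, batch-adjusted
# NB-GLM and BH adjustment.

test_that("filter threshold follows the median-library formula", {
  expect_equal(round(filter_threshold(10, 30e6), 2), 0.33)
  expect_equal(filter_threshold(10, 1e6), 10)
  expect_equal(filter_threshold(1, 1e6), 1)
  expect_error(filter_threshold(0, 1e6), "positive")
  expect_error(filter_threshold(10, -1), "positive")
})

test_that("expression filtering keeps boundary genes and matches brute force", {
  # constant library size of 1000 so the threshold sits exactly on g1
  g1 <- c(10L, 10L, 10L, 9L, 9L, 9L)   # at threshold in exactly 3 samples
  g2 <- c(10L, 10L, 9L, 9L, 9L, 9L)    # at threshold in only 2
  g3 <- rep(100L, 6)
  g4 <- 1000L - g1 - g2 - g3           # filler keeping all libraries equal
  counts <- toy_counts(rbind(g1, g2, g3, g4))
  groups <- rep(c("A", "B"), each = 3)
  flt <- filter_by_expression(counts, groups, min_count = 10)
  thr <- flt$threshold
  # brute-force re-scan
  m <- as_mat(counts)
  cpm <- sweep(m, 2, colSums(m), "/") * 1e6
  expect_setequal(flt$kept, rownames(m)[rowSums(cpm >= thr) >= 3])
  g1_cpm <- cpm[1, ]
  expect_true(sum(g1_cpm >= thr) == 3 && "g1" %in% flt$kept)
  expect_true("g2" %in% flt$removed)

  # monotone in min_count: raising it never adds genes
  flt2 <- filter_by_expression(counts, groups, min_count = 20)
  expect_true(all(flt2$kept %in% flt$kept))
})

test_that("TMM factors are 1 for identical and rescaled columns", {
  set.seed(11)
  col <- rpois(200, 50)
  same <- toy_counts(cbind(col, col, col))
  expect_equal(tmm_factors(same)$norm_factor, rep(1, 3), tolerance = 1e-12)

  scaled <- toy_counts(cbind(col, col * 2L, col))
  f <- tmm_factors(scaled)$norm_factor
  expect_equal(f, rep(1, 3), tolerance = 1e-12)
})

test_that("TMM matches a step-by-step oracle on a 20-gene toy", {
  set.seed(21)
  m <- matrix(rnbinom(20 * 4, size = 5, mu = 200), 20, 4)
  m[1:3, 2] <- m[1:3, 2] * 8L  # composition bias in sample 2
  counts <- toy_counts(m)
  res <- tmm_factors(counts, ref_sample = "s1")
  lib <- colSums(m)
  raw <- vapply(1:4, function(s) {
    if (s == 1) return(1)
    bf_tmm_factor(m[, s], m[, 1], lib[s], lib[1])
  }, numeric(1))
  expected <- raw / exp(mean(log(raw)))
  expect_equal(res$norm_factor, expected, tolerance = 1e-10)
})

test_that("TMM agrees with the established implementation", {
  skip_if_not_installed("edgeR")
  set.seed(31)
  m <- matrix(rnbinom(2000 * 6, size = 10, mu = 80), 2000, 6)
  m[1:100, 3] <- m[1:100, 3] * 5L
  counts <- toy_counts(m)
  ours <- tmm_factors(counts)
  theirs <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(ours$norm_factor, unname(theirs), tolerance = 0.02)
})

test_that("common dispersion is recovered by the moment estimator", {
  set.seed(41)
  # Poisson data -> phi near zero
  pois <- toy_counts(matrix(rpois(2000 * 16, 100), 2000, 16))
  groups <- rep(c("A", "B"), each = 8)
  expect_lte(estimate_common_dispersion(pois, groups), 0.01)

  # NB phi = 0.1 -> recovered within 0.03
  nb <- toy_counts(matrix(rnbinom(2000 * 16, size = 10, mu = 100), 2000, 16))
  phi_hat <- estimate_common_dispersion(nb, groups)
  expect_lt(abs(phi_hat - 0.1), 0.03)

  # constant counts -> floored
  const <- toy_counts(matrix(50L, 100, 6))
  expect_equal(estimate_common_dispersion(const, rep(c("A", "B"), each = 3)),
               1e-6)
})

test_that("identical groups give p = 1 and logFC = 0 everywhere", {
  set.seed(51)
  half <- matrix(rpois(50 * 4, 60), 50, 4)
  counts <- toy_counts(cbind(half, half))
  groups <- rep(c("A", "B"), each = 4)
  de <- nb_exact_test(counts, groups, dispersion = 0.1)
  expect_true(all(de$pvalue == 1))
  expect_true(all(de$logFC == 0))
})

test_that("swapping group labels negates logFC and preserves p", {
  sim <- nb_two_group(rep(c(50, 200), 10), rep(c(100, 150), 10), seed = 61)
  a <- nb_exact_test(sim$counts, sim$groups, dispersion = 0.1,
                     contrast = c("A", "B"))
  b <- nb_exact_test(sim$counts, sim$groups, dispersion = 0.1,
                     contrast = c("B", "A"))
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-12)
  expect_equal(a$logFC, -b$logFC, tolerance = 1e-12)
})

test_that("a strong planted effect is recovered with the right sign", {
  # 2-fold-and-more effect at moderate expression, 8 vs 8: the planted gene
  # must reach significance with correct sign in almost every replicate
  hits <- 0L; correct_sign <- 0L
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    mean1 <- rep(50, 200)
    mean2 <- mean1
    mean2[1] <- 200  # log2FC = 2 on the first gene
    sim <- nb_two_group(mean1, mean2, seed = 1000 + r)
    de <- nb_exact_test(sim$counts, sim$groups, dispersion = 0.1,
                        contrast = c("A", "B"))
    if (de$adj_pvalue[1] < 0.05) hits <- hits + 1L
    if (de$logFC[1] > 0) correct_sign <- correct_sign + 1L
  }
  expect_gte(hits / n_rep, 0.95)
  expect_equal(correct_sign, n_rep)
})

test_that("all-zero genes are reported as p = 1, logFC = 0", {
  m <- matrix(rpois(40, 30), 10, 4)
  m[4, ] <- 0L
  de <- nb_exact_test(toy_counts(m), rep(c("A", "B"), each = 2),
                      dispersion = 0.1)
  expect_equal(de$pvalue[4], 1)
  expect_equal(de$logFC[4], 0)
})

test_that("single-batch GLM agrees with the exact test on ranking", {
  set.seed(71)
  mean1 <- 10^runif(300, 1, 2.5)
  mean2 <- mean1 * 2^(rnorm(300, 0, 0.3))
  sim <- nb_two_group(mean1, mean2, seed = 72)
  exact <- nb_exact_test(sim$counts, sim$groups, dispersion = 0.1,
                         contrast = c("A", "B"))
  glm <- nb_glm_batch_test(sim$counts, sim$groups, batch = rep("b1", 16),
                           dispersion = 0.1, contrast = c("A", "B"))
  expect_gt(stats::cor(exact$pvalue, glm$pvalue, method = "spearman"), 0.9)
  expect_gt(stats::cor(exact$logFC, glm$logFC), 0.98)
})

test_that("batch adjustment removes batch-driven false positives", {
  set.seed(81)
  ng <- 400
  base <- 10^runif(ng, 1, 2.5)
  # two batches; 20% of genes shifted 2.5-fold in batch 2; no treatment effect
  shifted <- seq_len(ng) <= 80
  mu <- matrix(base, ng, 16)
  batch <- rep(c("b1", "b2"), each = 8)
  treatment <- rep(rep(c("ctrl", "trt"), each = 4), 2)
  mu[shifted, batch == "b2"] <- mu[shifted, batch == "b2"] * 2.5
  counts <- toy_counts(matrix(rnbinom(ng * 16, size = 10, mu = mu), ng, 16))
  adj <- nb_glm_batch_test(counts, treatment, batch, dispersion = 0.1,
                           contrast = c("ctrl", "trt"))
  expect_lt(mean(adj$pvalue < 0.05), 0.09)

  # a naive pooled two-group exact test on a confounded-ish design (treatment
  # imbalanced across batches) inflates false positives among shifted genes
  treatment_imb <- c(rep("ctrl", 6), rep("trt", 2), rep("ctrl", 2), rep("trt", 6))
  counts_imb <- counts
  naive <- nb_exact_test(counts_imb, treatment_imb, dispersion = 0.1,
                         contrast = c("ctrl", "trt"))
  adj2 <- nb_glm_batch_test(counts_imb, treatment_imb, batch, dispersion = 0.1,
                            contrast = c("ctrl", "trt"))
  fp_naive <- mean(naive$pvalue[shifted] < 0.05)
  fp_adj <- mean(adj2$pvalue[shifted] < 0.05)
  expect_gt(fp_naive, fp_adj + 0.2)
})

test_that("confounded designs are refused", {
  m <- toy_counts(matrix(rpois(80, 50), 10, 8))
  treatment <- rep(c("ctrl", "trt"), each = 4)
  batch <- treatment  # perfectly aliased
  expect_error(nb_glm_batch_test(m, treatment, batch, dispersion = 0.1),
               "aliased|confounded")
})

test_that("BH adjustment reproduces step-up arithmetic and its properties", {
  expect_equal(adjust_bh(0.04), 0.04)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  # order preservation and cap at 1 on random vectors
  set.seed(91)
  for (i in 1:20) {
    p <- runif(50)
    q <- adjust_bh(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    # order preservation: adjusted values are non-decreasing in p
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})
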