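# CPM computation, expression tiers, transcript-share accounting and
# marker correlation QC.

test_that("CPM matches direct arithmetic and columns sum to one million", {
  set.seed(42)
  m <- matrix(rpois(12, 50), 4)
  counts <- toy_counts(m)
  cpm <- as_mat(compute_cpm(counts))
  # independent brute-force evaluation
  expected <- m
  for (s in 1:3) expected[, s] <- m[, s] / sum(m[, s]) * 1e6
  expect_equal(unname(cpm), unname(expected), tolerance = 1e-12)
  expect_equal(unname(colSums(cpm)), rep(1e6, 3), tolerance = 1e-6)

  one <- toy_counts(matrix(c(10L, 999990L), 2))
  expect_equal(as_mat(compute_cpm(one))[1, 1], 10)

  zero <- toy_counts(matrix(c(0L, 0L), 1))
  expect_error(compute_cpm(zero), "s1")
})

test_that("tier assignment is total, ordered and matches the worked values", {
  expect_identical(as.character(expression_tier(7.8)), "lower_medium")
  expect_identical(as.character(expression_tier(0.05)), "residual")
  expect_identical(as.character(expression_tier(1000)), "top")
  # left-closed boundaries
  expect_identical(as.character(expression_tier(c(0, 0.1, 1, 10, 100))),
                   c("residual", "low", "lower_medium", "upper_medium", "high"))
  expect_error(expression_tier(-1), "non-negative")
  expect_true(is.ordered(expression_tier(5)))
})

test_that("tier summary accounts for genes and transcript shares", {
  # all genes at 5 CPM -> everything in lower_medium (CPM supplied directly)
  flat <- toy_counts(matrix(rep(5, 8), 4))
  ann <- toy_annotation(flat$gene_id)
  ts <- tier_summary(flat, ann)
  lm_row <- dplyr::filter(ts, tier == "lower_medium")
  expect_equal(lm_row$pct_genes, 100)
  expect_equal(lm_row$pct_transcripts, 100)

  # two genes at 1 and 9999 CPM -> transcript shares 0.01% / 99.99%
  two <- toy_counts(matrix(c(1, 9999), 2))
  ts2 <- tier_summary(two, toy_annotation(two$gene_id))
  expect_equal(dplyr::filter(ts2, tier == "lower_medium")$pct_transcripts,
               0.01, tolerance = 1e-9)
  expect_equal(dplyr::filter(ts2, tier == "top")$pct_transcripts, 99.99,
               tolerance = 1e-9)

  # percentages always close
  expect_equal(sum(ts2$pct_genes), 100, tolerance = 1e-9)
  expect_equal(sum(ts2$pct_transcripts), 100, tolerance = 1e-9)
})

test_that("tier summary gene proportions recover the simulated mixture", {
  w <- c(residual = 0, low = 0, lower_medium = 0.5, upper_medium = 0.3,
         high = 0.15, top = 0.05)
  sim <- simulate_counts(sim_config(n_genes = 3000, seed = 13, de_fraction = 0,
                                    batch_shift_sd = 0, tier_weights = w))
  ts <- tier_summary(compute_cpm(sim$counts), sim$annotation)
  obs <- ts$pct_genes / 100
  names(obs) <- as.character(ts$tier)
  # oracle: tier proportions implied by the true rates renormalized to the
  # realized library composition
  scale <- 1e6 / sum(sim$truth$genes$true_cpm)
  expected <- table(expression_tier(sim$truth$genes$true_cpm * scale)) /
    nrow(sim$truth$genes)
  for (tier in c("lower_medium", "upper_medium", "high")) {
    expect_lt(abs(obs[[tier]] - expected[[tier]]), 0.03)
  }
})

test_that("detected genes are those with any positive value", {
  m <- matrix(0L, 3, 4)
  m[2, 3] <- 1L
  counts <- toy_counts(m)
  det <- detected_genes(counts)
  expect_identical(det$detected, "g2")
  expect_setequal(det$undetected, c("g1", "g3"))
  # brute-force scan agreement on random data
  set.seed(7)
  r <- matrix(rbinom(50, 1, 0.2) * rpois(50, 3), 10)
  d2 <- detected_genes(toy_counts(r))
  expect_setequal(d2$detected, paste0("g", which(rowSums(r) > 0)))
})

test_that("marker QC classifies latent-factor modules and noise correctly", {
  set.seed(99)
  n_s <- 48
  z <- rnorm(n_s)
  related <- t(sapply(1:3, function(i) exp(z + rnorm(n_s, 0, 0.01)) * 50))
  noise <- matrix(rpois(5 * n_s, 50), 5)
  cpm <- toy_counts(rbind(related, noise),
                    genes = c("r1", "r2", "r3", paste0("n", 1:5)))
  sets <- tibble::tibble(
    set = rep(c("related", "unrelated"), c(3, 5)),
    gene_id = c("r1", "r2", "r3", paste0("n", 1:5)),
    expected_relationship = rep(c("high", "none"), c(3, 5)))
  qc <- marker_correlation_qc(cpm, sets)
  expect_true(all(dplyr::filter(qc$pairs, set == "related")$r > 0.95))
  expect_true(dplyr::filter(qc$sets, set == "related")$pass)
  expect_true(dplyr::filter(qc$sets, set == "unrelated")$pass)
  # missing markers reported, not fatal
  sets2 <- dplyr::add_row(sets, set = "related", gene_id = "absent",
                          expected_relationship = "high")
  qc2 <- marker_correlation_qc(cpm, sets2)
  expect_identical(dplyr::filter(qc2$sets, set == "related")$n_missing, 1L)
})

test_that("independent NB noise yields ~5% nominally significant pairs", {
  set.seed(123)
  n_s <- 48
  noise <- matrix(rnbinom(40 * n_s, size = 10, mu = 100), 40)
  cpm <- toy_counts(noise)
  sets <- tibble::tibble(set = "null", gene_id = cpm$gene_id,
                         expected_relationship = "none")
  qc <- marker_correlation_qc(cpm, sets)
  expect_lt(max(abs(qc$pairs$r)), 0.6)
  expect_lt(abs(mean(qc$pairs$p < 0.05) - 0.05), 0.03)
})

test_that("a gene against itself correlates perfectly", {
  set.seed(5)
  m <- matrix(rpois(20, 30), 2, 10)
  m[2, ] <- m[1, ]
  cpm <- toy_counts(m, genes = c("dup1", "dup2"))
  sets <- tibble::tibble(set = "dup", gene_id = c("dup1", "dup2"),
                         expected_relationship = "high")
  qc <- marker_correlation_qc(cpm, sets)
  expect_equal(qc$pairs$r, 1)
  # and fewer than 3 samples is an error
  expect_error(marker_correlation_qc(toy_counts(matrix(1:4, 2)), sets),
               "3 samples")
})

test_that("Pearson r here equals the covariance formula to 1e-12", {
  set.seed(17)
  x <- rnorm(12); y <- rnorm(12)
  cpm <- toy_counts(rbind(abs(x) * 10, abs(y) * 10), genes = c("ga", "gb"))
  qc <- marker_correlation_qc(
    cpm, tibble::tibble(set = "s", gene_id = c("ga", "gb"),
                        expected_relationship = "none"))
  xx <- abs(x) * 10; yy <- abs(y) * 10
  r_direct <- sum((xx - mean(xx)) * (yy - mean(yy))) /
    sqrt(sum((xx - mean(xx))^2) * sum((yy - mean(yy))^2))
  expect_equal(qc$pairs$r, r_direct, tolerance = 1e-12)
})
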