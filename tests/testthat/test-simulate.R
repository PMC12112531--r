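# Count simulator: determinism, noise-free limit, effect-size rule,
# tier mixture, marker-module correlation; atlas and reference-list
# generators.

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 200, seed = 11)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth$genes, b$truth$genes)
  c2 <- simulate_counts(sim_config(n_genes = 200, seed = 12))
  expect_false(identical(a$counts, c2$counts))
})

test_that("in the noise-free limit sample CPM approaches true CPM", {
  cfg <- sim_config(
    n_genes = 300, seed = 5, de_fraction = 0, batch_shift_sd = 0,
    nb_dispersion = 1e-8, lib_size_cv = 0, lib_size_mean = 5e6,
    marker_modules = list(),
    tier_weights = c(residual = 0, low = 0, lower_medium = 0.4,
                     upper_medium = 0.4, high = 0.2, top = 0)
  )
  sim <- simulate_counts(cfg)
  cpm <- as_mat(compute_cpm(sim$counts))
  true <- sim$truth$genes$true_cpm
  # realized CPM is the drawn rate renormalized to the realized library
  scale <- 1e6 / sum(true)
  rel_err <- abs(rowMeans(cpm) - true * scale) / (true * scale)
  expect_lt(stats::median(rel_err), 0.05)
})

test_that("planted |log2FC| follows the linear-in-log10CPM rule", {
  cfg <- sim_config(n_genes = 4000, seed = 9, de_fraction = 0.3,
                    de_effect_rule = c(a = 2, b = 0.5))
  sim <- simulate_counts(cfg)
  truth <- sim$truth$genes
  de <- dplyr::filter(truth, is_de, abs(true_lfc) > 0,
                      2 - 0.5 * log10(true_cpm) > 0)
  fit <- stats::lm(abs(true_lfc) ~ log10(true_cpm), data = de)
  expect_equal(unname(stats::coef(fit)[2]), -0.5, tolerance = 1e-8)
  # DE indicator consistent with the truth contract
  expect_identical(truth$is_de, truth$true_lfc != 0)
})

test_that("tier proportions of true CPM match the configured mixture", {
  w <- c(residual = 0.46, low = 0.20, lower_medium = 0.16,
         upper_medium = 0.12, high = 0.055, top = 0.005)
  sim <- simulate_counts(sim_config(n_genes = 20000, seed = 21,
                                    tier_weights = w))
  obs <- table(factor(sim$truth$genes$tier, levels = names(w)))
  gof <- stats::chisq.test(obs, p = w)
  expect_gt(gof$p.value, 0.001)
  # tier labels agree with the tier implied by the drawn CPM
  expect_identical(as.character(expression_tier(sim$truth$genes$true_cpm)),
                   sim$truth$genes$tier)
})

test_that("marker-module genes correlate more within than between modules", {
  cfg <- sim_config(n_genes = 1000, seed = 31, de_fraction = 0,
                    marker_modules = list(
                      list(label = "m1", n_genes = 4L, loading = 1),
                      list(label = "m2", n_genes = 4L, loading = 1)))
  sim <- simulate_counts(cfg)
  cpm <- as_mat(compute_cpm(sim$counts))
  mods <- split(sim$truth$genes$gene_id, sim$truth$genes$module)
  within_r <- function(ids) {
    cc <- stats::cor(t(cpm[ids, ]))
    mean(cc[upper.tri(cc)])
  }
  between <- mean(stats::cor(t(cpm[mods$m1, ]), t(cpm[mods$m2, ])))
  expect_gt(within_r(mods$m1), between)
  expect_gt(within_r(mods$m2), between)
  expect_gt(within_r(mods$m1), 0.5)
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(n_genes = -1), "n_genes")
  expect_error(sim_config(de_fraction = 1.5), "de_fraction")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(tier_weights = c(residual = 1)), "tier_weights")
})

test_that("atlas generator plants genes at the requested specificity", {
  cats <- list(immune = c("MGL1", "PVM"), vascular = c("ABC", "PER1"),
               neurons = c("TEGLU1", "TEGLU2"))
  atl <- simulate_atlas(60, cats, n_specific_per_category = 4,
                        specificity_level = 3, seed = 8)
  planted <- dplyr::filter(atl$truth, !is.na(category))
  sc <- score_specificity(planted$symbol, atl$atlas, atl$category_map)
  expect_true(all(sc$score >= 3 - 1e-9))
  expect_identical(sc$best_category, planted$category)

  flat <- simulate_atlas(30, cats, 4, specificity_level = 1, seed = 9)
  planted1 <- dplyr::filter(flat$truth, !is.na(category))
  sc1 <- score_specificity(planted1$symbol, flat$atlas, flat$category_map)
  expect_true(all(sc1$score >= 1 - 1e-9))
  expect_true(all(sc1$score <= 1 + 1e-9))

  expect_error(simulate_atlas(10, list()), "non-empty")
})

test_that("a zero out-of-category maximum triggers the substitution rule", {
  atlas <- tibble::tibble(symbol = "g", MGL1 = 2.21, ABC = 0)
  map <- tibble::tibble(cell_type = c("MGL1", "ABC"),
                        category = c("immune", "vascular"))
  expect_equal(specificity_score(c(MGL1 = 2.21, ABC = 0), "immune", map),
               2.21 / 1e-4)
  sc <- score_specificity("g", atlas, map)
  expect_equal(sc$score, 22100)
})

test_that("reference-list generator follows the binomial direction model", {
  pool <- sprintf("Gene%03d", 1:500)
  all_up <- simulate_reference_list(pool, 50, direction_probability = 1,
                                    seed = 3)
  expect_true(all(direction_preference(all_up$n_up, all_up$n_down) == "up"))

  # p = 0.5 with n reports each: fraction labelled preferential matches the
  # binomial tail, computed independently
  big <- simulate_reference_list(pool, 400, direction_probability = 0.5,
                                 n_reports_range = c(8L, 8L), seed = 4)
  lab <- direction_preference(big$n_up, big$n_down)
  expected <- 2 * stats::pbinom(ceiling(0.75 * 8) - 1, 8, 0.5,
                                lower.tail = FALSE)
  expect_equal(mean(lab != "none"), expected, tolerance = 0.06)

  expect_identical(nrow(simulate_reference_list(pool, 0)), 0L)
  expect_error(simulate_reference_list(pool[1:3], 10), "exceeds")
})
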