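# Synthetic bulk RNA-seq data with the statistical structure the analysis
# assumes: heavy-tailed per-gene expression spanning six CPM tiers, NB
# sampling noise, planted treatment effects that shrink with mean
# expression, per-timepoint batch shifts, and correlated marker-gene
# modules. Ground truth is returned alongside for parameter-recovery tests.

#' Simulation configuration
#'
#' Builds and validates the configuration consumed by [simulate_counts()].
#' The defaults emulate the design of a six-group chronic corticosterone
#' experiment: three treatment durations (5, 14 and 28 days), a control and
#' a corticosterone group per duration, eight sequenced animals per group.
#' Library sizes are drawn lognormal around one million reads -- a
#' desk-scale depth; the filtering threshold formula scales with the median
#' library size, so analyses behave the same as at full sequencing depth.
#'
#' Per-gene true expression (in CPM) is drawn from a mixture over the six
#' expression tiers (residual < 0.1, low 0.1-1, lower medium 1-10, upper
#' medium 10-100, high 100-1000, top >= 1000 CPM), log10-uniform within each
#' tier. Planted treatment effects follow the rule
#' `|log2FC| = a - b * log10(true CPM)`, truncated at zero, so that highly
#' expressed genes respond with smaller fold changes; signs are random.
#' Batch shifts are additive log2 offsets applied to a random subset of
#' genes in every sample of a timepoint. Marker modules are small gene sets
#' that share a per-sample lognormal latent factor and therefore correlate
#' across samples.
#'
#' @param n_genes Number of genes.
#' @param groups Data frame with columns `label`, `treatment` (`"control"`
#'   or `"cort"`), `timepoint` (days) and `n_samples`.
#' @param lib_size_mean,lib_size_cv Mean and coefficient of variation of the
#'   lognormal library-size distribution (reads).
#' @param tier_weights Named numeric vector of mixture weights over the six
#'   tiers (`residual`, `low`, `lower_medium`, `upper_medium`, `high`,
#'   `top`); must sum to 1.
#' @param nb_dispersion Common NB dispersion phi (variance = mu + phi*mu^2).
#' @param de_fraction Fraction of genes with planted treatment effects.
#' @param de_effect_rule Numeric `c(a, b)` of the effect-size rule above.
#' @param batch_shift_sd SD (log2 scale) of the per-timepoint batch offsets;
#'   0 disables the batch effect.
#' @param batch_gene_fraction Fraction of genes receiving a batch offset in
#'   each timepoint.
#' @param marker_modules List of module descriptors, each a list with
#'   `label`, `n_genes` and `loading` (latent-factor loading, >= 0).
#' @param seed Integer seed; all randomness in [simulate_counts()] derives
#'   from it.
#' @return A validated configuration object (class `cortseq_sim_config`).
#' @export
sim_config <- function(n_genes = 5000,
                       groups = default_groups(),
                       lib_size_mean = 1e6,
                       lib_size_cv = 0.1,
                       tier_weights = c(residual = 0.46, low = 0.20,
                                        lower_medium = 0.16, upper_medium = 0.12,
                                        high = 0.055, top = 0.005),
                       nb_dispersion = 0.1,
                       de_fraction = 0.05,
                       de_effect_rule = c(a = 2, b = 0.5),
                       batch_shift_sd = 0.5,
                       batch_gene_fraction = 0.05,
                       marker_modules = default_marker_modules(),
                       seed = 1L) {
  check_positive_scalar(n_genes, "n_genes")
  if (!is.data.frame(groups) ||
      !all(c("label", "treatment", "timepoint", "n_samples") %in% names(groups))) {
    abort("`groups` must have columns label, treatment, timepoint, n_samples.")
  }
  if (!all(groups$treatment %in% c("control", "cort"))) {
    abort("`groups$treatment` must be 'control' or 'cort'.")
  }
  if (any(groups$n_samples < 1)) abort("`groups$n_samples` must be positive.")
  check_positive_scalar(lib_size_mean, "lib_size_mean")
  if (lib_size_cv < 0) abort("`lib_size_cv` must be non-negative.")
  tiers <- c("residual", "low", "lower_medium", "upper_medium", "high", "top")
  if (!setequal(names(tier_weights), tiers)) {
    abort("`tier_weights` must be named with the six expression tiers.")
  }
  tier_weights <- tier_weights[tiers]
  if (any(tier_weights < 0) || abs(sum(tier_weights) - 1) > 1e-8) {
    abort("`tier_weights` must be non-negative and sum to 1.")
  }
  check_positive_scalar(nb_dispersion, "nb_dispersion")
  check_fraction(de_fraction, "de_fraction")
  if (length(de_effect_rule) != 2L || any(!is.finite(de_effect_rule))) {
    abort("`de_effect_rule` must be numeric c(a, b).")
  }
  if (batch_shift_sd < 0) abort("`batch_shift_sd` must be non-negative.")
  check_fraction(batch_gene_fraction, "batch_gene_fraction")
  for (m in marker_modules) {
    if (!all(c("label", "n_genes", "loading") %in% names(m)) ||
        m$n_genes < 2 || m$loading < 0) {
      abort("Each marker module needs label, n_genes >= 2 and loading >= 0.")
    }
  }
  structure(
    list(n_genes = as.integer(n_genes), groups = as_tibble(groups),
         lib_size_mean = lib_size_mean, lib_size_cv = lib_size_cv,
         tier_weights = tier_weights, nb_dispersion = nb_dispersion,
         de_fraction = de_fraction,
         de_effect_rule = stats::setNames(as.numeric(de_effect_rule), c("a", "b")),
         batch_shift_sd = batch_shift_sd,
         batch_gene_fraction = batch_gene_fraction,
         marker_modules = marker_modules, seed = as.integer(seed)),
    class = "cortseq_sim_config"
  )
}

#' Default experimental design: 2 treatments x 3 timepoints x 8 samples
#' @return Tibble of group descriptors.
#' @export
default_groups <- function() {
  tidyr::expand_grid(timepoint = c(5L, 14L, 28L),
                     treatment = c("control", "cort")) |>
    dplyr::mutate(label = paste0(.data$treatment, "_", .data$timepoint, "d"),
                  n_samples = 8L) |>
    dplyr::select("label", "treatment", "timepoint", "n_samples")
}

#' Default marker modules used by the simulator
#'
#' Three functionally related gene pairs/triples sharing a strong latent
#' factor, emulating e.g. immediate-early, hemoglobin and ribosomal-protein
#' gene modules whose correlated expression is used for dataset validation.
#' @return List of module descriptors.
#' @export
default_marker_modules <- function() {
  list(list(label = "ieg", n_genes = 3L, loading = 1),
       list(label = "hemoglobin", n_genes = 3L, loading = 1),
       list(label = "ribosomal", n_genes = 3L, loading = 1))
}

tier_bounds_log10 <- function() {
  # log10 CPM bounds used for within-tier uniform draws; the open-ended
  # tiers get a finite span wide enough to look heavy-tailed.
  list(residual = c(-3, -1), low = c(-1, 0), lower_medium = c(0, 1),
       upper_medium = c(1, 2), high = c(2, 3), top = c(3, 4))
}

#' Simulate a count matrix with ground truth
#'
#' Draws per-gene true CPM from the configured tier mixture, plants
#' treatment effects, batch shifts and marker-module latent factors, and
#' samples NB counts with mean
#' `lib_size * trueCPM/1e6 * 2^(effects) * module factor` and common
#' dispersion phi. Deterministic under a fixed config seed.
#'
#' @param config A [sim_config()] object.
#' @return List of class `cortseq_sim` with elements `counts` (tibble),
#'   `metadata` (tibble: sample_id, group, treatment, timepoint),
#'   `annotation` (synthetic annotation tibble), and `truth` (list with
#'   per-gene and per-sample truth tibbles).
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 200, seed = 7))
#' sim$counts[1:3, 1:4]
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "cortseq_sim_config")) {
    abort("`config` must be built with sim_config().")
  }
  set.seed(config$seed)
  ng <- config$n_genes
  gene_id <- sprintf("SIMG%05d", seq_len(ng))

  tiers <- names(config$tier_weights)
  tier <- sample(tiers, ng, replace = TRUE, prob = config$tier_weights)
  b <- tier_bounds_log10()
  log10cpm <- vapply(tier, function(t) stats::runif(1, b[[t]][1], b[[t]][2]),
                     numeric(1))
  true_cpm <- 10^log10cpm

  # samples
  meta <- config$groups |>
    dplyr::rowwise() |>
    dplyr::reframe(sample_id = paste0(.data$label, "_s", seq_len(.data$n_samples)),
                   group = .data$label, treatment = .data$treatment,
                   timepoint = .data$timepoint)
  ns <- nrow(meta)
  lib_sd <- sqrt(log(1 + config$lib_size_cv^2))
  lib_mu <- log(config$lib_size_mean) - lib_sd^2 / 2
  lib_size <- stats::rlnorm(ns, lib_mu, lib_sd)

  # planted treatment effects: |log2FC| shrinks with mean expression
  n_de <- round(config$de_fraction * ng)
  de_idx <- if (n_de > 0) sample.int(ng, n_de) else integer(0)
  a <- config$de_effect_rule[["a"]]; bb <- config$de_effect_rule[["b"]]
  true_lfc <- numeric(ng)
  if (n_de > 0) {
    mag <- pmax(0, a - bb * log10cpm[de_idx])
    sgn <- sample(c(-1, 1), n_de, replace = TRUE)
    true_lfc[de_idx] <- mag * sgn
  }

  # marker modules: disjoint from the DE set, drawn from medium tiers so
  # they are comfortably detected
  module <- rep(NA_character_, ng)
  eligible <- setdiff(which(tier %in% c("lower_medium", "upper_medium", "high")),
                      de_idx)
  for (m in config$marker_modules) {
    if (length(eligible) < m$n_genes) {
      abort(sprintf("Not enough eligible genes for marker module '%s'.", m$label))
    }
    pick <- sample(eligible, m$n_genes)
    module[pick] <- m$label
    eligible <- setdiff(eligible, pick)
  }
  loadings <- stats::setNames(
    vapply(config$marker_modules, `[[`, numeric(1), "loading"),
    vapply(config$marker_modules, `[[`, character(1), "label")
  )

  # per-timepoint batch offsets on a random gene subset
  timepoints <- unique(meta$timepoint)
  batch_shift <- matrix(0, ng, length(timepoints),
                        dimnames = list(gene_id, as.character(timepoints)))
  if (config$batch_shift_sd > 0 && config$batch_gene_fraction > 0) {
    for (tp in as.character(timepoints)) {
      hit <- sample.int(ng, round(config$batch_gene_fraction * ng))
      batch_shift[hit, tp] <- stats::rnorm(length(hit), 0, config$batch_shift_sd)
    }
  }

  # per-sample latent factors for marker modules
  z <- matrix(stats::rnorm(length(loadings) * ns, 0, 0.5), length(loadings), ns,
              dimnames = list(names(loadings), meta$sample_id))

  mu <- matrix(0, ng, ns, dimnames = list(gene_id, meta$sample_id))
  is_cort <- meta$treatment == "cort"
  for (s in seq_len(ns)) {
    log2_eff <- (if (is_cort[s]) true_lfc else rep(0, ng)) +
      batch_shift[, as.character(meta$timepoint[s])]
    fac <- rep(1, ng)
    in_mod <- !is.na(module)
    if (any(in_mod)) {
      fac[in_mod] <- exp(loadings[module[in_mod]] * z[module[in_mod], s])
    }
    mu[, s] <- lib_size[s] * true_cpm / 1e6 * 2^log2_eff * fac
  }

  size <- 1 / max(config$nb_dispersion, 1e-12)
  counts <- matrix(stats::rnbinom(ng * ns, size = size, mu = mu), ng, ns,
                   dimnames = dimnames(mu))

  biotypes <- c("protein_coding", "lncRNA", "processed_pseudogene", "TEC")
  ann <- tibble(
    gene_id = gene_id,
    symbol = paste0("Sym", seq_len(ng)),
    biotype = sample(biotypes, ng, replace = TRUE, prob = c(0.5, 0.25, 0.2, 0.05)),
    description = ifelse(stats::runif(ng) < 0.3, "predicted gene (synthetic)", "")
  ) |> validate_annotation()

  truth_genes <- tibble(
    gene_id = gene_id, tier = tier, true_cpm = true_cpm,
    true_lfc = true_lfc, is_de = true_lfc != 0, module = module
  )
  truth_samples <- dplyr::bind_cols(
    meta, tibble(true_lib_size = lib_size)
  )

  structure(
    list(counts = matrix_to_tibble(counts) |>
           dplyr::mutate(dplyr::across(-"gene_id", as.integer)),
         metadata = as_tibble(meta), annotation = ann,
         truth = list(genes = truth_genes, samples = truth_samples,
                      batch_shift = matrix_to_tibble(batch_shift)),
         config = config),
    class = "cortseq_sim"
  )
}

#' Simulate a cell-type expression atlas with planted specific genes
#'
#' Generates a gene-by-cell-type table of normalized expression values in
#' which, per category, a set of planted genes has its within-category
#' maximum approximately `specificity_level` times the out-of-category
#' maximum; the remaining genes are near-uniform across cell types.
#'
#' @param n_genes Total genes in the atlas.
#' @param categories Named list mapping category label to a character vector
#'   of cell-type ids (the category map); must be non-empty.
#' @param n_specific_per_category Planted specific genes per category.
#' @param specificity_level Target in/out expression ratio (>= 1).
#' @param seed Integer seed.
#' @return List with `atlas` (tibble: `symbol` + one column per cell type),
#'   `category_map` (tibble: cell_type, category) and `truth` (tibble:
#'   symbol, category of planted genes; NA for background genes).
#' @export
simulate_atlas <- function(n_genes, categories, n_specific_per_category = 5,
                           specificity_level = 3, seed = 1L) {
  if (length(categories) == 0) abort("`categories` must be a non-empty list.")
  if (specificity_level < 1) abort("`specificity_level` must be >= 1.")
  set.seed(seed)
  cell_types <- unlist(categories, use.names = FALSE)
  if (anyDuplicated(cell_types)) abort("Cell types must be unique across categories.")
  n_cat <- length(categories)
  n_planted <- n_cat * n_specific_per_category
  if (n_planted > n_genes) abort("Too many planted genes for `n_genes`.")

  symbol <- paste0("Atl", seq_len(n_genes))
  base <- matrix(stats::runif(n_genes * length(cell_types), 0.5, 1.5),
                 n_genes, length(cell_types),
                 dimnames = list(symbol, cell_types))
  truth <- rep(NA_character_, n_genes)
  slot <- 1L
  for (cat in names(categories)) {
    for (k in seq_len(n_specific_per_category)) {
      in_ct <- categories[[cat]]
      out_ct <- setdiff(cell_types, in_ct)
      base[slot, ] <- stats::runif(length(cell_types), 0.2, 1)
      # force the in-category max to the target ratio of the out max; the
      # remaining in-category cells stay at or below the out max
      out_max <- if (length(out_ct) > 0) max(base[slot, out_ct]) else 1
      base[slot, in_ct] <- stats::runif(length(in_ct), 0.2, 1) * out_max
      top_ct <- if (length(in_ct) == 1) in_ct else sample(in_ct, 1)
      base[slot, top_ct] <- specificity_level * out_max
      truth[slot] <- cat
      slot <- slot + 1L
    }
  }
  map <- tibble(
    cell_type = cell_types,
    category = rep(names(categories), lengths(categories))
  )
  list(atlas = dplyr::bind_cols(tibble(symbol = symbol),
                                as_tibble(base, .name_repair = "minimal")),
       category_map = map,
       truth = tibble(symbol = symbol, category = truth))
}

#' Simulate a referential gene list with per-gene direction tallies
#'
#' Each member receives `n` literature reports of which `k ~ Binomial(n, p)`
#' are up-reports, emulating referential lists of stress- or
#' glucocorticoid-responsive genes with direction tallies.
#'
#' @param gene_pool Character vector of candidate symbols.
#' @param n_members Number of list members to draw from the pool.
#' @param direction_probability Probability `p` that any single report is an
#'   up-report.
#' @param n_reports_range Integer range `c(lo, hi)`; each member's total
#'   report count is uniform on it.
#' @param label List label.
#' @param seed Integer seed.
#' @return Tibble: `symbol`, `n_up`, `n_down`, `list` label.
#' @export
simulate_reference_list <- function(gene_pool, n_members,
                                    direction_probability = 0.5,
                                    n_reports_range = c(3L, 8L),
                                    label = "synthetic", seed = 1L) {
  check_fraction(direction_probability, "direction_probability")
  if (n_members > length(gene_pool)) {
    abort("`n_members` exceeds the size of `gene_pool`.")
  }
  set.seed(seed)
  if (n_members == 0) {
    return(tibble(symbol = character(), n_up = integer(), n_down = integer(),
                  list = character()))
  }
  members <- sample(gene_pool, n_members)
  span <- seq(n_reports_range[1], n_reports_range[2])
  n_rep <- span[sample.int(length(span), n_members, replace = TRUE)]
  n_up <- stats::rbinom(n_members, n_rep, direction_probability)
  tibble(symbol = members, n_up = n_up, n_down = n_rep - n_up, list = label)
}
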