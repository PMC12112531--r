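# Differential expression: expression filtering with the median-library
# threshold rule, TMM normalization, a conditional negative-binomial exact
# test for two groups, a batch-adjusted NB log-linear model fitted by IRLS
# with a likelihood-ratio test, and FDR adjustment. The NB machinery is
# implemented here from first principles (common dispersion, exact
# conditioning on per-group totals) rather than delegated, so that every
# numerical choice is visible and testable.

#' CPM filtering threshold from the minimum-count rule
#'
#' `threshold = min_count / median_lib_size * 1e6`. With a minimum count of
#' 10 and a median library of 30 million reads this yields 0.33 CPM.
#'
#' @param min_count Minimum count a gene must reach (reads).
#' @param median_lib_size Median raw library size (reads).
#' @return The CPM threshold (single number).
#' @examples
#' filter_threshold(10, 30e6)
#' @export
filter_threshold <- function(min_count, median_lib_size) {
  check_positive_scalar(min_count, "min_count")
  check_positive_scalar(median_lib_size, "median_lib_size")
  min_count / median_lib_size * 1e6
}

#' Filter genes by expression level
#'
#' Keeps genes whose CPM reaches the [filter_threshold()] (computed from
#' the median library size of the data) in at least `n_min` samples, where
#' `n_min` is the smallest group size. The boundary is inclusive.
#'
#' @param counts Counts tibble.
#' @param groups Character/factor vector assigning each sample column to a
#'   group (in column order), or a metadata tibble with `sample_id` and
#'   `group` columns.
#' @param min_count Minimum-count parameter of the threshold rule.
#' @return List with `kept` and `removed` gene-id vectors, `threshold`
#'   (CPM), `n_min`, and `observed_min_mean_cpm` (the smallest mean CPM
#'   among kept genes -- the effective mean-expression cut-off realised by
#'   the filter).
#' @export
filter_by_expression <- function(counts, groups, min_count = 10) {
  mat <- counts_matrix(counts)
  groups <- resolve_groups(groups, mat)
  if (length(unique(groups)) < 2) abort("At least two groups are required.")
  totals <- colSums(mat)
  thr <- filter_threshold(min_count, stats::median(totals))
  n_min <- min(table(groups))
  cpm <- sweep(mat, 2, totals, "/") * 1e6
  keep <- rowSums(cpm >= thr) >= n_min
  mean_cpm <- rowMeans(cpm)
  list(kept = rownames(mat)[keep], removed = rownames(mat)[!keep],
       threshold = thr, n_min = as.integer(n_min),
       observed_min_mean_cpm = if (any(keep)) min(mean_cpm[keep]) else NA_real_)
}

resolve_groups <- function(groups, mat) {
  if (is.data.frame(groups)) {
    check_metadata(mat, groups)
    if (!"group" %in% names(groups)) {
      abort("Metadata must contain a `group` column.")
    }
    groups <- groups$group[match(colnames(mat), groups$sample_id)]
  }
  if (length(groups) != ncol(mat)) {
    abort("`groups` must assign one group per sample column.")
  }
  as.character(groups)
}

#' Trimmed mean of M-values normalization factors
#'
#' Computes per-sample TMM scaling factors with the published defaults:
#' the reference sample is the one whose upper-quartile CPM is closest to
#' the mean upper quartile; per sample, log ratios (M) and average log
#' abundances (A) against the reference are computed over genes expressed
#' in both; 30% of genes are trimmed on each side by M and 5% by A; the
#' remaining M values are averaged with inverse-variance (delta-method)
#' weights. Factors are rescaled so their geometric mean is 1.
#'
#' @param counts Counts tibble.
#' @param ref_sample Optional sample id to use as reference; default picks
#'   the upper-quartile-closest sample.
#' @param trim_m,trim_a Trim fractions for M and A (defaults 0.30 / 0.05).
#' @return Tibble: `sample_id`, `lib_size`, `norm_factor`,
#'   `effective_lib_size` (= lib_size * norm_factor).
#' @export
tmm_factors <- function(counts, ref_sample = NULL, trim_m = 0.30, trim_a = 0.05) {
  mat <- counts_matrix(counts)
  if (ncol(mat) < 2) abort("TMM requires at least two samples.")
  lib <- colSums(mat)
  if (any(lib <= 0)) abort("All library sizes must be positive.")
  if (is.null(ref_sample)) {
    uq <- apply(sweep(mat, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
    ref_sample <- colnames(mat)[which.min(abs(uq - mean(uq)))]
  }
  if (!ref_sample %in% colnames(mat)) {
    abort(sprintf("Reference sample '%s' not found.", ref_sample))
  }
  yr <- mat[, ref_sample]
  nr <- lib[[ref_sample]]
  f <- vapply(colnames(mat), function(s) {
    if (s == ref_sample) return(1)
    y <- mat[, s]; n <- lib[[s]]
    ok <- y > 0 & yr > 0
    if (!any(ok)) {
      abort(sprintf("Sample '%s' shares no expressed genes with the reference.", s))
    }
    m <- log2((y[ok] / n) / (yr[ok] / nr))
    a <- 0.5 * log2((y[ok] / n) * (yr[ok] / nr))
    w <- (n - y[ok]) / (n * y[ok]) + (nr - yr[ok]) / (nr * yr[ok])
    keep_m <- rank(m) > floor(length(m) * trim_m) &
      rank(m) <= length(m) - floor(length(m) * trim_m)
    keep_a <- rank(a) > floor(length(a) * trim_a) &
      rank(a) <= length(a) - floor(length(a) * trim_a)
    keep <- keep_m & keep_a
    if (!any(keep)) return(1)
    2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
  }, numeric(1))
  f <- f / geomean(f)
  tibble(sample_id = colnames(mat), lib_size = unname(lib),
         norm_factor = unname(f),
         effective_lib_size = unname(lib * f))
}

#' Method-of-moments common NB dispersion
#'
#' Pools, over all genes and within every group with at least two samples,
#' the moment identity `var = mu + phi * mu^2` on library-equalized counts:
#' `phi = sum(v - m) / sum(m^2)`, floored at 1e-6. Counts are equalized to
#' the geometric mean of the effective library sizes before the moments are
#' taken, so unequal sequencing depth does not masquerade as dispersion.
#'
#' @param counts Counts tibble.
#' @param groups Group assignment (vector or metadata tibble; see
#'   [filter_by_expression()]).
#' @param norm Optional [tmm_factors()] tibble; default computes it.
#' @return Estimated dispersion phi (single number).
#' @export
estimate_common_dispersion <- function(counts, groups, norm = NULL) {
  mat <- counts_matrix(counts)
  groups <- resolve_groups(groups, mat)
  sizes <- table(groups)
  if (all(sizes < 2)) abort("Dispersion needs at least one group with >= 2 samples.")
  if (is.null(norm)) norm <- tmm_factors(counts)
  eff <- norm$effective_lib_size[match(colnames(mat), norm$sample_id)]
  eq <- sweep(mat, 2, eff, "/") * geomean(eff)
  num <- 0; den <- 0
  for (g in names(sizes)[sizes >= 2]) {
    sub <- eq[, groups == g, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    use <- m > 0
    num <- num + sum(v[use] - m[use])
    den <- den + sum(m[use]^2)
  }
  max(num / den, 1e-6)
}

# Round half to even, preserving non-negativity.
round_half_even <- function(x) round(x)

# Library equalization used by the exact test: rescale each sample's counts
# to the geometric mean of the effective library sizes, then round.
equalize_counts <- function(mat, eff) {
  target <- geomean(eff)
  round_half_even(sweep(mat, 2, eff, "/") * target)
}

#' Conditional NB exact test for two groups
#'
#' For each gene, counts are rescaled to a common (geometric-mean)
#' effective library size and summed within each group. Writing the group
#' sums as NB variables (`Y1 ~ NB(n1*m, phi/n1)`, `Y2 ~ NB(n2*m, phi/n2)`
#' with `m` the per-sample mean under the null), the two-sided p-value is
#' the total conditional probability, given the overall total, of all
#' outcomes at most as likely as the observed split. Log2 fold changes are
#' computed from normalized group mean CPM with a small prior count (0.125
#' per group) so zero counts stay finite.
#'
#' @param counts Counts tibble (already filtered).
#' @param groups Group assignment (vector or metadata tibble) with exactly
#'   two levels; `contrast` orders them.
#' @param dispersion Common NB dispersion phi; estimated from the data when
#'   `NULL`.
#' @param norm Optional [tmm_factors()] tibble; default computes it.
#' @param contrast Character length-2: `c(control, treated)`. Fold changes
#'   are treated over control. Defaults to the sorted group levels.
#' @param comparison Label stored in the result (e.g. `"5d"`).
#' @param annotation Optional annotation tibble used to attach symbols.
#' @return A `cortseq_de` tibble: `gene_id`, `symbol` (if available),
#'   `logFC`, `log10_mean_cpm`, `pvalue`, `adj_pvalue`, `direction`,
#'   `comparison`. Attributes store dispersion, the normalization table and
#'   the contrast.
#' @export
nb_exact_test <- function(counts, groups, dispersion = NULL, norm = NULL,
                          contrast = NULL, comparison = "exact",
                          annotation = NULL) {
  mat <- counts_matrix(counts)
  groups <- resolve_groups(groups, mat)
  lev <- unique(groups)
  if (length(lev) != 2) abort("nb_exact_test requires exactly two groups.")
  if (is.null(contrast)) contrast <- sort(lev)
  if (!setequal(contrast, lev)) abort("`contrast` must name the two groups.")
  if (is.null(norm)) norm <- tmm_factors(counts)
  eff <- norm$effective_lib_size[match(colnames(mat), norm$sample_id)]
  if (anyNA(eff)) abort("Normalization table does not cover all samples.")
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(counts, groups, norm = norm)
  }
  phi <- max(dispersion, 1e-10)

  eq <- equalize_counts(mat, eff)
  i1 <- groups == contrast[1]; i2 <- groups == contrast[2]
  n1 <- sum(i1); n2 <- sum(i2)
  t1 <- rowSums(eq[, i1, drop = FALSE])
  t2 <- rowSums(eq[, i2, drop = FALSE])

  pvals <- vapply(seq_len(nrow(eq)), function(g) {
    exact_nb_pvalue(t1[g], t2[g], n1, n2, phi)
  }, numeric(1))

  cpm <- sweep(mat, 2, eff, "/") * 1e6
  prior_cpm <- 0.125 / mean(eff) * 1e6
  m1 <- rowMeans(cpm[, i1, drop = FALSE])
  m2 <- rowMeans(cpm[, i2, drop = FALSE])
  logfc <- log2((m2 + prior_cpm) / (m1 + prior_cpm))
  mean_cpm <- rowMeans(cpm)

  de_result(rownames(mat), logfc, mean_cpm, pvals, comparison,
            annotation = annotation, dispersion = phi, norm = norm,
            contrast = contrast)
}

# Two-sided conditional exact NB p-value for group totals t1, t2 from
# groups of n1 and n2 equalized samples with common dispersion phi. The
# group totals are treated as NB with size n_i/phi; conditioning on
# t = t1 + t2 gives the exact null distribution of the split.
exact_nb_pvalue <- function(t1, t2, n1, n2, phi) {
  t <- t1 + t2
  if (t == 0) return(1)
  m <- t / (n1 + n2)
  size1 <- n1 / phi; mu1 <- n1 * m
  size2 <- n2 / phi; mu2 <- n2 * m
  # restrict to the region carrying essentially all conditional mass
  lo <- max(0, min(stats::qnbinom(1e-14, size1, mu = mu1),
                   t - stats::qnbinom(1 - 1e-14, size2, mu = mu2), t1))
  hi <- min(t, max(stats::qnbinom(1 - 1e-14, size1, mu = mu1),
                   t - stats::qnbinom(1e-14, size2, mu = mu2), t1))
  y <- lo:hi
  logp <- stats::dnbinom(y, size1, mu = mu1, log = TRUE) +
    stats::dnbinom(t - y, size2, mu = mu2, log = TRUE)
  logp <- logp - max(logp)
  p <- exp(logp)
  obs <- p[y == t1]
  min(1, sum(p[p <= obs * (1 + 1e-10)]) / sum(p))
}

#' Batch-adjusted NB log-linear model with likelihood-ratio test
#'
#' Fits, per gene, a negative-binomial log-linear model
#' `log mu = offset(log effective lib) + batch + treatment` by iteratively
#' reweighted least squares with known common dispersion, and tests the
#' treatment coefficient with a likelihood-ratio chi-square against the
#' batch-only reduced model. With a single batch the model reduces to
#' two-group NB regression.
#'
#' @param counts Counts tibble (already filtered).
#' @param treatment Per-sample treatment assignment (vector in column
#'   order, or metadata tibble with `sample_id` and `treatment`).
#' @param batch Per-sample batch assignment (vector, or metadata tibble
#'   column `timepoint`/`batch`).
#' @param dispersion Common NB dispersion phi; estimated when `NULL`.
#' @param norm Optional [tmm_factors()] tibble.
#' @param contrast Character length-2 `c(control, treated)` ordering of the
#'   treatment levels; defaults to sorted levels.
#' @param comparison Label stored in the result (default `"pooled"`).
#' @param annotation Optional annotation tibble used to attach symbols.
#' @return A `cortseq_de` tibble (see [nb_exact_test()]).
#' @export
nb_glm_batch_test <- function(counts, treatment, batch, dispersion = NULL,
                              norm = NULL, contrast = NULL,
                              comparison = "pooled", annotation = NULL) {
  mat <- counts_matrix(counts)
  if (is.data.frame(treatment)) {
    meta <- treatment
    check_metadata(mat, meta)
    ord <- match(colnames(mat), meta$sample_id)
    treatment <- as.character(meta$treatment[ord])
    if (is.character(batch) && length(batch) == 1 && batch %in% names(meta)) {
      batch <- as.character(meta[[batch]][ord])
    }
  }
  treatment <- as.character(treatment)
  batch <- as.character(batch)
  if (length(treatment) != ncol(mat) || length(batch) != ncol(mat)) {
    abort("`treatment` and `batch` must assign one value per sample.")
  }
  lev <- unique(treatment)
  if (length(lev) != 2) abort("nb_glm_batch_test requires two treatment levels.")
  if (is.null(contrast)) contrast <- sort(lev)
  if (!setequal(contrast, lev)) abort("`contrast` must name the two treatments.")
  # aliasing check: the treatment indicator must not be expressible by batch
  tt <- as.integer(treatment == contrast[2])
  if (length(unique(batch)) > 1) {
    fit_alias <- stats::lm.fit(stats::model.matrix(~ factor(batch)), tt)
    if (max(abs(fit_alias$residuals)) < 1e-8) {
      abort("Design is confounded: treatment is aliased with batch.")
    }
  }
  if (is.null(norm)) norm <- tmm_factors(counts)
  eff <- norm$effective_lib_size[match(colnames(mat), norm$sample_id)]
  if (anyNA(eff)) abort("Normalization table does not cover all samples.")
  groups_for_phi <- paste(treatment, batch, sep = ".")
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(counts, groups_for_phi, norm = norm)
  }
  phi <- max(dispersion, 1e-10)

  off <- log(eff)
  if (length(unique(batch)) > 1) {
    x_full <- stats::model.matrix(~ factor(batch) + tt)
    x_red <- stats::model.matrix(~ factor(batch))
  } else {
    # single batch: plain two-group NB regression
    x_full <- stats::model.matrix(~ tt)
    x_red <- stats::model.matrix(~ 1, data = data.frame(tt))
  }
  trt_col <- ncol(x_full)

  res <- vapply(seq_len(nrow(mat)), function(g) {
    y <- mat[g, ]
    full <- nb_irls(y, x_full, off, phi)
    red <- nb_irls(y, x_red, off, phi)
    lrt <- max(0, red$deviance - full$deviance)
    c(beta = unname(full$coef[trt_col]),
      p = stats::pchisq(lrt, df = 1, lower.tail = FALSE))
  }, numeric(2))

  cpm <- sweep(mat, 2, eff, "/") * 1e6
  mean_cpm <- rowMeans(cpm)
  logfc <- res["beta", ] / log(2)

  de_result(rownames(mat), logfc, mean_cpm, res["p", ], comparison,
            annotation = annotation, dispersion = phi, norm = norm,
            contrast = contrast)
}

# IRLS fit of an NB log-linear model with known dispersion phi.
# Returns coefficients and the NB deviance (saturated-model reference).
nb_irls <- function(y, x, offset, phi, max_iter = 50, tol = 1e-8) {
  eta <- log(pmax(y, 0.5)) - offset
  beta <- qr.coef(qr(x), eta)
  beta[is.na(beta)] <- 0
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta) + offset
    eta <- pmin(pmax(eta, -700), 700)
    mu <- exp(eta)
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- stats::lm.wfit(x, z, w)
    beta_new <- fit$coefficients
    beta_new[is.na(beta_new)] <- 0
    dev <- nb_deviance(y, exp(pmin(pmax(drop(x %*% beta_new) + offset,
                                        -700), 700)), phi)
    if (!is.finite(dev)) break
    if (abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      beta <- beta_new
      dev_old <- dev
      break
    }
    beta <- beta_new
    dev_old <- dev
  }
  list(coef = beta, deviance = nb_deviance(y, exp(pmin(pmax(
    drop(x %*% beta) + offset, -700), 700)), phi))
}

nb_deviance <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-12)
  term1 <- ifelse(y > 0, y * log(y / mu), 0)
  term2 <- (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu))
  2 * sum(term1 - term2)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; monotone and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04))
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  stats::p.adjust(p, method = "BH")
}

# Assemble a DE result tibble with the shared column contract.
de_result <- function(gene_id, logfc, mean_cpm, pvals, comparison,
                      annotation = NULL, dispersion = NA_real_, norm = NULL,
                      contrast = NULL) {
  out <- tibble(
    gene_id = gene_id,
    logFC = unname(logfc),
    log10_mean_cpm = log10(pmax(unname(mean_cpm), 1e-12)),
    pvalue = pmin(pmax(unname(pvals), 0), 1)
  ) |>
    dplyr::mutate(
      adj_pvalue = adjust_bh(.data$pvalue),
      direction = dplyr::case_when(.data$logFC > 0 ~ "up",
                                   .data$logFC < 0 ~ "down",
                                   TRUE ~ NA_character_),
      comparison = comparison
    )
  if (!is.null(annotation)) {
    ann <- validate_annotation(annotation)
    out <- dplyr::left_join(out, dplyr::select(ann, "gene_id", "symbol"),
                            by = "gene_id") |>
      dplyr::relocate("symbol", .after = "gene_id")
  }
  structure(out, class = c("cortseq_de", class(out)),
            dispersion = dispersion, norm = norm, contrast = contrast)
}

#' Significant genes of a DE result
#'
#' @param de A `cortseq_de` tibble.
#' @param alpha Adjusted-p cut-off (default 0.05).
#' @return The significant subset, same columns.
#' @export
significant_genes <- function(de, alpha = 0.05) {
  dplyr::filter(as_tibble(de), .data$adj_pvalue < alpha)
}

#' Write a DE result table as TSV
#' @param de A `cortseq_de` tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_de <- function(de, path) {
  readr::write_tsv(as_tibble(de), path, progress = FALSE)
  invisible(path)
}
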