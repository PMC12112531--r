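# Transcript budget: the net effect of treatment on total transcriptomic
# activity, computed on raw counts (not CPM) from the DE calls, plus the
# Mann-Whitney U test on per-sample totals.

#' Per-sample total transcript counts
#'
#' @param counts Counts tibble.
#' @return Tibble: `sample_id`, `total`.
#' @export
total_counts_per_sample <- function(counts) {
  mat <- counts_matrix(counts)
  tibble(sample_id = colnames(mat), total = unname(colSums(mat)))
}

#' Transcript budget of a set of differentially expressed genes
#'
#' For every DE gene the difference between the mean raw count in treated
#' and control samples is computed. Differences are summed over
#' up-regulated genes (transcripts gained) and, in absolute value, over
#' down-regulated genes (transcripts lost); the net change and all three
#' quantities as percentages of the mean control total complete the
#' budget.
#'
#' @param counts Counts tibble (raw counts, unfiltered scale).
#' @param de DE tibble with `gene_id` and `direction` columns (typically
#'   the significant subset).
#' @param control_ids,treated_ids Character vectors of sample ids.
#' @return A `cortseq_budget` list: `gained`, `lost`, `net`, `pct_gained`,
#'   `pct_lost`, `pct_net`, `mean_control_total`, `n_up`, `n_down`, and
#'   `per_gene` (tibble of per-gene mean differences).
#' @examples
#' counts <- tibble::tibble(gene_id = "g1", c1 = 100L, c2 = 100L,
#'                          t1 = 300L, t2 = 300L)
#' de <- tibble::tibble(gene_id = "g1", direction = "up")
#' budget_from_de(counts, de, c("c1", "c2"), c("t1", "t2"))$gained
#' @export
budget_from_de <- function(counts, de, control_ids, treated_ids) {
  mat <- counts_matrix(counts)
  if (length(control_ids) == 0 || length(treated_ids) == 0) {
    abort("Both sample sets must be non-empty.")
  }
  missing_s <- setdiff(c(control_ids, treated_ids), colnames(mat))
  if (length(missing_s) > 0) {
    abort(sprintf("Sample(s) not in counts: %s.",
                  paste(missing_s, collapse = ", ")))
  }
  de <- as_tibble(de)
  if (nrow(de) == 0) {
    per_gene <- tibble(gene_id = character(), direction = character(),
                       mean_control = numeric(), mean_treated = numeric(),
                       delta = numeric())
    mean_total <- mean(colSums(mat[, control_ids, drop = FALSE]))
    return(new_budget(0, 0, per_gene, mean_total))
  }
  missing_g <- setdiff(de$gene_id, rownames(mat))
  if (length(missing_g) > 0) {
    abort(sprintf("DE gene(s) absent from counts: %s.",
                  paste(utils::head(missing_g, 5L), collapse = ", ")))
  }
  sub <- mat[de$gene_id, , drop = FALSE]
  per_gene <- tibble(
    gene_id = de$gene_id,
    direction = de$direction,
    mean_control = rowMeans(sub[, control_ids, drop = FALSE]),
    mean_treated = rowMeans(sub[, treated_ids, drop = FALSE])
  ) |>
    dplyr::mutate(delta = .data$mean_treated - .data$mean_control)
  gained <- sum(per_gene$delta[per_gene$direction == "up"])
  lost <- sum(abs(per_gene$delta[per_gene$direction == "down"]))
  mean_total <- mean(colSums(mat[, control_ids, drop = FALSE]))
  new_budget(gained, lost, per_gene, mean_total)
}

new_budget <- function(gained, lost, per_gene, mean_total) {
  structure(list(
    gained = gained, lost = lost, net = gained - lost,
    pct_gained = 100 * gained / mean_total,
    pct_lost = 100 * lost / mean_total,
    pct_net = 100 * (gained - lost) / mean_total,
    mean_control_total = mean_total,
    n_up = sum(per_gene$direction == "up"),
    n_down = sum(per_gene$direction == "down"),
    per_gene = per_gene
  ), class = "cortseq_budget")
}

#' @export
print.cortseq_budget <- function(x, ...) {
  cat("Transcript budget\n")
  cat(sprintf("  up-regulated genes:   %d, transcripts gained %.0f (%.2f%% of control total)\n",
              x$n_up, x$gained, x$pct_gained))
  cat(sprintf("  down-regulated genes: %d, transcripts lost   %.0f (%.2f%% of control total)\n",
              x$n_down, x$lost, x$pct_lost))
  cat(sprintf("  net change:           %.0f (%.2f%% of mean control total %.0f)\n",
              x$net, x$pct_net, x$mean_control_total))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test reporting `U = min(U1, U2)` with midrank tie
#' handling. Without ties and with both samples of size at most 12 the
#' p-value is exact (doubled smaller tail of the exact U distribution);
#' otherwise the normal approximation with the tie-corrected variance is
#' used, without continuity correction.
#'
#' @param x,y Numeric samples (non-empty).
#' @return Tibble with one row: `U`, `p`, `method` (`"exact"` or
#'   `"normal"`).
#' @examples
#' mann_whitney_u(1:4, 5:8) # complete separation: U = 0, p = 2/choose(8,4)
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("Both samples must be non-empty.")
  if (any(!is.finite(c(x, y)))) abort("Samples must be finite.")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  ties <- any(duplicated(c(x, y)))
  if (!ties && n1 <= 12 && n2 <= 12) {
    p <- min(1, 2 * stats::pwilcox(u, n1, n2))
    method <- "exact"
  } else {
    pooled <- table(r)
    tie_term <- sum(pooled^3 - pooled)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u1 - n1 * n2 / 2) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  tibble(U = u, p = p, method = method)
}

#' Per-timepoint U tests on total transcript counts
#'
#' Runs [mann_whitney_u()] on the per-sample totals of control versus
#' treated samples within each timepoint.
#'
#' @param counts Counts tibble.
#' @param metadata Metadata tibble with `sample_id`, `treatment`,
#'   `timepoint`.
#' @return Tibble: `timepoint`, `U`, `p`, `method`, `n_control`,
#'   `n_treated`.
#' @export
total_count_tests <- function(counts, metadata) {
  totals <- total_counts_per_sample(counts) |>
    dplyr::left_join(metadata, by = "sample_id")
  totals |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::group_map(function(df, key) {
      ctrl <- df$total[df$treatment == "control"]
      trt <- df$total[df$treatment != "control"]
      dplyr::bind_cols(tibble(timepoint = key$timepoint),
                       mann_whitney_u(ctrl, trt),
                       tibble(n_control = length(ctrl), n_treated = length(trt)))
    }) |> dplyr::bind_rows()
}
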