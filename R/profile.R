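# Global transcriptome profile: CPM computation, six-tier expression
# categorization, transcript-share and biotype accounting, and marker-based
# correlation QC.

#' Expression tier names, in order
#' @return Character vector of the six tiers.
#' @export
expression_tiers <- function() {
  c("residual", "low", "lower_medium", "upper_medium", "high", "top")
}

#' Compute counts per million
#'
#' `cpm[g, s] = counts[g, s] / library_total[s] * 1e6`, where the library
#' total is the column sum of raw counts; every CPM column therefore sums
#' to exactly one million.
#'
#' @param counts Counts tibble (`gene_id` + sample columns).
#' @return CPM tibble with the same shape.
#' @examples
#' counts <- tibble::tibble(gene_id = c("a", "b"), s1 = c(10L, 90L))
#' compute_cpm(counts)
#' @export
compute_cpm <- function(counts) {
  mat <- counts_matrix(counts)
  totals <- colSums(mat)
  if (any(totals <= 0)) {
    abort(sprintf("Zero library total for sample(s): %s.",
                  paste(colnames(mat)[totals <= 0], collapse = ", ")))
  }
  matrix_to_tibble(sweep(mat, 2, totals, "/") * 1e6)
}

#' Assign expression tiers from mean CPM
#'
#' The six tiers partition `[0, Inf)` into left-closed, right-open decade
#' intervals: residual `[0, 0.1)`, low `[0.1, 1)`, lower medium `[1, 10)`,
#' upper medium `[10, 100)`, high `[100, 1000)` and top `[1000, Inf)`.
#'
#' @param mean_cpm Numeric vector of non-negative mean CPM values.
#' @return Ordered factor with the six tier levels.
#' @examples
#' expression_tier(c(0.05, 7.8, 1000))
#' @export
expression_tier <- function(mean_cpm) {
  if (any(!is.finite(mean_cpm)) || any(mean_cpm < 0)) {
    abort("`mean_cpm` must be finite and non-negative.")
  }
  cut(mean_cpm, breaks = c(0, 0.1, 1, 10, 100, 1000, Inf),
      labels = expression_tiers(), right = FALSE, ordered_result = TRUE)
}

#' Genes detected in at least one sample
#'
#' A gene is detected when its CPM (equivalently its raw count) exceeds
#' zero in at least one sample.
#'
#' @param cpm CPM (or counts) tibble.
#' @return List with `detected` and `undetected` character vectors of gene
#'   ids.
#' @export
detected_genes <- function(cpm) {
  mat <- counts_matrix(cpm, "cpm")
  det <- rowSums(mat > 0) > 0
  list(detected = rownames(mat)[det], undetected = rownames(mat)[!det])
}

#' Per-tier gene counts, transcript shares and biotype composition
#'
#' Computes, for each expression tier over detected genes: the gene count
#' and its percentage of all detected genes; the tier's share of total
#' transcripts (sum of per-gene mean CPM in the tier as a percentage of the
#' summed mean CPM of all detected genes); and the biotype composition
#' (percentage of protein-coding, predicted, pseudogene, lncRNA and other
#' genes within the tier; predicted status is independent of biotype, so
#' these percentages may overlap).
#'
#' @param cpm CPM tibble.
#' @param annotation Annotation tibble covering every gene (see
#'   [validate_annotation()]).
#' @return Tibble with one row per tier.
#' @export
tier_summary <- function(cpm, annotation) {
  mat <- counts_matrix(cpm, "cpm")
  if (nrow(mat) == 0 || ncol(mat) == 0) abort("`cpm` must be non-empty.")
  annotation <- validate_annotation(annotation)
  missing <- setdiff(rownames(mat), annotation$gene_id)
  if (length(missing) > 0) {
    abort(sprintf("Gene id(s) absent from annotation: %s.",
                  paste(utils::head(missing, 5L), collapse = ", ")))
  }
  mean_cpm <- rowMeans(mat)
  det <- rowSums(mat > 0) > 0
  genes <- tibble(gene_id = rownames(mat), mean_cpm = mean_cpm)[det, ] |>
    dplyr::mutate(tier = expression_tier(.data$mean_cpm)) |>
    dplyr::left_join(annotation, by = "gene_id")

  total_genes <- nrow(genes)
  total_cpm <- sum(genes$mean_cpm)
  genes |>
    dplyr::group_by(tier = .data$tier, .drop = FALSE) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      pct_genes = 100 * dplyr::n() / total_genes,
      pct_transcripts = 100 * sum(.data$mean_cpm) / total_cpm,
      pct_protein_coding = pct_of(.data$biotype == "protein_coding"),
      pct_predicted = pct_of(.data$is_predicted),
      pct_pseudogene = pct_of(stringr::str_detect(.data$biotype, "pseudogene")),
      pct_lncRNA = pct_of(.data$biotype == "lncRNA"),
      .groups = "drop"
    )
}

pct_of <- function(flag) {
  if (length(flag) == 0) return(NA_real_)
  100 * mean(flag, na.rm = TRUE)
}

#' Marker-set correlation QC
#'
#' Computes all pairwise Pearson correlations (with two-sided p-values)
#' across samples within each marker set and classifies the set against its
#' expected relationship. Sets of functionally related genes are expected
#' to correlate highly; unrelated sets should show weak or insignificant
#' correlations. Marker genes absent from the matrix are reported, not
#' fatal.
#'
#' @param cpm CPM tibble.
#' @param marker_sets Tibble with columns `set`, `gene_id` and
#'   `expected_relationship` (one of `"high"`, `"loose"`, `"none"`; constant
#'   within a set).
#' @param thresholds Named list of classification cut-offs: `high_r`
#'   (minimum pairwise r for "high"), `none_r` and `none_p` ("none" passes
#'   when every pair has |r| < `none_r` or p > `none_p`); "loose" passes
#'   when the median r lies in `[loose_lo, high_r)`.
#' @return List with `pairs` (tibble of per-pair r and p) and `sets`
#'   (tibble: set, expected, n_genes, n_missing, median_r, pass).
#' @export
marker_correlation_qc <- function(cpm, marker_sets,
                                  thresholds = list(high_r = 0.6, none_r = 0.4,
                                                    none_p = 0.05,
                                                    loose_lo = 0.2)) {
  mat <- counts_matrix(cpm, "cpm")
  if (ncol(mat) < 3) abort("At least 3 samples are required for correlation QC.")
  need <- c("set", "gene_id", "expected_relationship")
  if (!all(need %in% names(marker_sets))) {
    abort("`marker_sets` must have columns set, gene_id, expected_relationship.")
  }
  pairs <- marker_sets |>
    dplyr::group_by(.data$set) |>
    dplyr::group_map(function(df, key) {
      present <- intersect(df$gene_id, rownames(mat))
      if (length(present) < 2) return(NULL)
      combos <- utils::combn(present, 2)
      purrr::map_dfr(seq_len(ncol(combos)), function(i) {
        ct <- stats::cor.test(mat[combos[1, i], ], mat[combos[2, i], ])
        tibble(set = key$set, gene_a = combos[1, i], gene_b = combos[2, i],
               r = unname(ct$estimate), p = ct$p.value)
      })
    }) |> dplyr::bind_rows()

  sets <- marker_sets |>
    dplyr::group_by(set = .data$set,
                    expected = .data$expected_relationship) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_missing = sum(!.data$gene_id %in% rownames(mat)),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      pairs |> dplyr::group_by(.data$set) |>
        dplyr::summarise(median_r = stats::median(.data$r),
                         min_r = min(.data$r),
                         all_none_ok = all(abs(.data$r) < thresholds$none_r |
                                             .data$p > thresholds$none_p),
                         .groups = "drop"),
      by = "set"
    ) |>
    dplyr::mutate(pass = dplyr::case_when(
      is.na(.data$median_r) ~ NA,
      .data$expected == "high" ~ .data$min_r >= thresholds$high_r,
      .data$expected == "none" ~ .data$all_none_ok,
      .data$expected == "loose" ~ .data$median_r >= thresholds$loose_lo &
        .data$median_r < thresholds$high_r,
      TRUE ~ NA
    )) |>
    dplyr::select(-"all_none_ok")
  list(pairs = pairs, sets = sets)
}
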