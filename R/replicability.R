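# Cross-timepoint replicability: Venn region counts, direction-consistent
# replicable gene sets, and the fold-change-versus-expression relationship.

#' Venn region counts over 2-4 gene sets
#'
#' Counts, for every intersection region of the supplied sets, the number
#' of genes with exactly that membership pattern. Region counts sum to the
#' union size.
#'
#' @param sets Named list (2-4 elements, unique labels) of character
#'   vectors of gene ids, or of data frames with a `gene_id` column.
#' @return Tibble: one logical membership column per set, `region` label
#'   (e.g. `"A&B"`), and `n`.
#' @examples
#' venn_counts(list(A = c("g1", "g2"), B = c("g2", "g3")))
#' @export
venn_counts <- function(sets) {
  if (length(sets) < 2 || length(sets) > 4) abort("Provide 2 to 4 sets.")
  if (is.null(names(sets)) || anyDuplicated(names(sets)) || any(names(sets) == "")) {
    abort("Sets must carry unique, non-empty labels.")
  }
  ids <- purrr::map(sets, function(s) {
    if (is.data.frame(s)) unique(as.character(s$gene_id)) else unique(as.character(s))
  })
  universe <- unique(unlist(ids))
  member <- purrr::map(ids, function(s) universe %in% s) |>
    dplyr::bind_cols()
  out <- member |>
    dplyr::group_by(dplyr::across(dplyr::everything())) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop")
  flags <- as.matrix(out[names(sets)])
  out$region <- apply(flags, 1, function(row) {
    paste(names(sets)[as.logical(row)], collapse = "&")
  })
  dplyr::relocate(out, "region", "n", .after = dplyr::last_col())
}

#' Replicable genes across treatment durations
#'
#' Genes significant at two or more timepoints with the same direction of
#' significant change (non-significant timepoints are ignored). Each
#' replicable gene is labelled by its tier: significant in all three
#' timepoints or in exactly two.
#'
#' @param timepoint_sets Named list (>= 2) of significant-gene tables, each
#'   a data frame with `gene_id` and `direction` columns (e.g. from
#'   [significant_genes()]).
#' @return Tibble: `gene_id`, `direction`, `n_significant`, `tier`
#'   (`"all_three"` when significant in every one of three supplied sets,
#'   else `"exactly_two"`), plus `conflict` listing genes excluded for
#'   direction conflicts as an attribute.
#' @export
replicable_genes <- function(timepoint_sets) {
  if (length(timepoint_sets) < 2) abort("At least two timepoint sets are needed.")
  all_sig <- purrr::imap_dfr(timepoint_sets, function(df, label) {
    tibble(gene_id = as.character(df$gene_id),
           direction = as.character(df$direction), timepoint = label)
  })
  per_gene <- all_sig |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_significant = dplyr::n(),
                     n_dir = dplyr::n_distinct(.data$direction),
                     direction = .data$direction[1], .groups = "drop")
  conflict <- per_gene |>
    dplyr::filter(.data$n_significant >= 2, .data$n_dir > 1) |>
    dplyr::pull("gene_id")
  out <- per_gene |>
    dplyr::filter(.data$n_significant >= 2, .data$n_dir == 1) |>
    dplyr::mutate(tier = dplyr::if_else(
      .data$n_significant >= length(timepoint_sets) &
        length(timepoint_sets) >= 3,
      "all_three", "exactly_two")) |>
    dplyr::select("gene_id", "direction", "n_significant", "tier")
  attr(out, "conflict") <- conflict
  out
}

#' Correlation between effect magnitude and expression level
#'
#' Pearson correlation (with two-sided p) between `|log2FC|` and log10 mean
#' CPM over the significant genes of a DE result. A negative correlation
#' means that highly expressed genes respond with smaller fold changes.
#'
#' @param de A DE tibble (`logFC`, `log10_mean_cpm`, `adj_pvalue` columns).
#' @param alpha Adjusted-p cut-off selecting the significant genes; set to
#'   `Inf` to use all rows.
#' @return Tibble with one row: `r`, `p`, `n_genes`.
#' @export
fc_vs_expression_correlation <- function(de, alpha = 0.05) {
  sig <- dplyr::filter(as_tibble(de), .data$adj_pvalue < alpha)
  if (nrow(sig) < 3) abort("Need at least 3 significant genes.")
  x <- abs(sig$logFC); y <- sig$log10_mean_cpm
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Zero variance in |logFC| or expression; correlation undefined.")
  }
  ct <- stats::cor.test(x, y)
  tibble(r = unname(ct$estimate), p = ct$p.value, n_genes = nrow(sig))
}
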