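# Comparison of DE results with referential gene lists (glucocorticoid
# core/extended, stress-duration categories, PTSD): symbol updating,
# per-replicability-tier overlap, and direction-preference rules.

#' Update gene symbols through a synonym map
#'
#' Replaces obsolete symbols by their current official symbol. Current
#' symbols (map values) are fixed points; symbols appearing neither as an
#' old nor a current symbol are left unchanged and listed as unresolved.
#'
#' @param symbols Character vector.
#' @param synonym_map Tibble with `old` and `current` columns (many old
#'   symbols may map to one current symbol; an old symbol mapping to two
#'   different current symbols is an error).
#' @return List: `updated` (character vector, same length), `unresolved`
#'   (symbols unknown to the map), `n_updated`.
#' @export
update_symbols <- function(symbols, synonym_map) {
  if (!all(c("old", "current") %in% names(synonym_map))) {
    abort("`synonym_map` must have `old` and `current` columns.")
  }
  conflicts <- synonym_map |>
    dplyr::distinct(.data$old, .data$current) |>
    dplyr::count(.data$old, name = "n") |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    abort(sprintf("Conflicting synonym entries for: %s.",
                  paste(conflicts$old, collapse = ", ")))
  }
  symbols <- as.character(symbols)
  hit <- match(symbols, synonym_map$old)
  updated <- ifelse(is.na(hit), symbols, synonym_map$current[hit])
  known <- symbols %in% synonym_map$old | symbols %in% synonym_map$current
  list(updated = updated,
       unresolved = unique(symbols[!known]),
       n_updated = sum(!is.na(hit) & updated != symbols))
}

#' Preferential direction of a reference-list member
#'
#' Two rules are used by the referential lists. The stress rule labels a
#' gene preferentially up-regulated when at least 75% of its reports are
#' up-reports (down symmetric). The glucocorticoid rule labels it up when
#' up-reports are at least three times as frequent as down-reports (down
#' symmetric). Both boundaries are inclusive.
#'
#' @param n_up,n_down Non-negative report tallies (vectorized; not both
#'   zero).
#' @param rule `"stress"` (75% rule) or `"glucocorticoid"` (3x rule).
#' @param threshold Fraction for the stress rule (default 0.75).
#' @return Character vector in `{"up", "down", "none"}`.
#' @examples
#' direction_preference(3, 1)                         # "up" (75% boundary)
#' direction_preference(6, 2, rule = "glucocorticoid") # "up" (3x boundary)
#' @export
direction_preference <- function(n_up, n_down, rule = c("stress", "glucocorticoid"),
                                 threshold = 0.75) {
  rule <- match.arg(rule)
  if (any(n_up < 0 | n_down < 0)) abort("Tallies must be non-negative.")
  if (any(n_up + n_down == 0)) abort("At least one report is required per gene.")
  if (rule == "stress") {
    frac <- n_up / (n_up + n_down)
    dplyr::case_when(frac >= threshold ~ "up",
                     frac <= 1 - threshold ~ "down",
                     TRUE ~ "none")
  } else {
    dplyr::case_when(n_up >= 3 * n_down ~ "up",
                     n_down >= 3 * n_up ~ "down",
                     TRUE ~ "none")
  }
}

#' Overlap between DE results and a referential gene list
#'
#' Intersects the significant genes of each replicability tier with the
#' reference-list members and tabulates, per tier: the overlap count, the
#' percentage of the tier explained by the list, and -- for overlapping
#' genes whose list entry has a preferential direction -- how many DE
#' directions agree with it.
#'
#' @param de_by_tier Named list of DE tables (tibbles with `symbol` and
#'   `direction` columns), one per replicability tier (e.g. `all_three`,
#'   `exactly_two`, `one`, `pooled_only`).
#' @param reference Reference tibble: `symbol`, `n_up`, `n_down` (and
#'   optionally `list`).
#' @param rule Direction-preference rule for the list (see
#'   [direction_preference()]).
#' @param synonym_map Optional synonym map applied to both sides first.
#' @return List: `by_tier` tibble (`tier`, `n_tier`, `n_overlap`,
#'   `pct_overlap` to one decimal, `n_with_preference`, `n_consistent`)
#'   and `genes` (per-gene overlap records).
#' @export
overlap_with_reference <- function(de_by_tier, reference,
                                   rule = c("stress", "glucocorticoid"),
                                   synonym_map = NULL) {
  rule <- match.arg(rule)
  if (is.null(names(de_by_tier))) abort("`de_by_tier` must be a named list.")
  ref <- as_tibble(reference)
  if (!all(c("symbol", "n_up", "n_down") %in% names(ref))) {
    abort("`reference` needs symbol, n_up and n_down columns.")
  }
  if (!is.null(synonym_map)) {
    ref$symbol <- update_symbols(ref$symbol, synonym_map)$updated
  }
  ref$preference <- direction_preference(ref$n_up, ref$n_down, rule = rule)

  empty_genes <- tibble(tier = character(), symbol = character(),
                        direction = character(), preference = character())
  genes <- purrr::imap_dfr(de_by_tier, function(df, tier) {
    df <- as_tibble(df)
    if (nrow(df) == 0) return(NULL)
    sym <- as.character(df$symbol)
    if (!is.null(synonym_map)) sym <- update_symbols(sym, synonym_map)$updated
    hit <- match(sym, ref$symbol)
    keep <- !is.na(hit)
    if (!any(keep)) return(NULL)
    tibble(tier = tier, symbol = sym[keep],
           direction = as.character(df$direction)[keep],
           preference = ref$preference[hit[keep]])
  })
  genes <- dplyr::bind_rows(empty_genes, genes)

  by_tier <- purrr::imap_dfr(de_by_tier, function(df, tier) {
    sub <- if (nrow(genes) > 0) dplyr::filter(genes, .data$tier == !!tier)
           else genes
    n_tier <- nrow(as_tibble(df))
    with_pref <- sub$preference %in% c("up", "down")
    tibble(
      tier = tier, n_tier = n_tier, n_overlap = nrow(sub),
      pct_overlap = round(if (n_tier > 0) 100 * nrow(sub) / n_tier else NA_real_, 1),
      n_with_preference = sum(with_pref),
      n_consistent = sum(with_pref & sub$direction == sub$preference)
    )
  })
  list(by_tier = by_tier, genes = genes)
}
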