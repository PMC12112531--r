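# Cell-expression specificity: the ratio between the highest expression of
# a gene within a cell-type category and the highest expression found in
# cells of all remaining categories, computed against a brain cell atlas.

#' Specificity score of one gene for one category
#'
#' `score = max(in-category expression) / max(out-of-category expression)`,
#' with an out-of-category maximum of zero replaced by `zero_sub` so the
#' ratio stays finite. A score of 1 means at least two categories reach the
#' gene's maximal expression; large scores indicate expression confined to
#' the category.
#'
#' @param expression Named numeric vector: normalized expression of one
#'   gene per cell type (names are cell-type ids), or a one-row atlas
#'   tibble slice.
#' @param category Category label to score.
#' @param category_map Tibble with `cell_type` and `category` columns
#'   covering every cell type of `expression`.
#' @param zero_sub Replacement for a zero out-of-category maximum
#'   (default 0.0001).
#' @return The specificity score (single positive number).
#' @examples
#' expr <- c(MGL1 = 2.21, ABC = 0.0141)
#' map <- tibble::tibble(cell_type = c("MGL1", "ABC"),
#'                       category = c("immune", "vascular"))
#' specificity_score(expr, "immune", map) # 156.7 to one decimal
#' @export
specificity_score <- function(expression, category, category_map,
                              zero_sub = 1e-4) {
  if (is.data.frame(expression)) {
    expression <- unlist(expression[setdiff(names(expression), "symbol")])
  }
  if (is.null(names(expression))) {
    abort("`expression` must be named by cell type.")
  }
  if (any(expression < 0, na.rm = TRUE)) abort("Expression must be non-negative.")
  if (!all(c("cell_type", "category") %in% names(category_map))) {
    abort("`category_map` must have cell_type and category columns.")
  }
  unmapped <- setdiff(names(expression), category_map$cell_type)
  if (length(unmapped) > 0) {
    abort(sprintf("Cell type(s) missing from category map: %s.",
                  paste(utils::head(unmapped, 5L), collapse = ", ")))
  }
  in_ct <- category_map$cell_type[category_map$category == category]
  in_ct <- intersect(in_ct, names(expression))
  if (length(in_ct) == 0) {
    abort(sprintf("Category '%s' has no cell types in the expression vector.",
                  category))
  }
  out_ct <- setdiff(names(expression), in_ct)
  in_max <- max(expression[in_ct], na.rm = TRUE)
  out_max <- if (length(out_ct) == 0) zero_sub else
    max(expression[out_ct], na.rm = TRUE)
  if (out_max == 0) out_max <- zero_sub
  in_max / out_max
}

#' Score every gene against every category and keep the best
#'
#' For each requested gene the specificity score is computed for every
#' category in the map; the highest score and its category are retained.
#' Genes absent from the atlas (after optional synonym updating) yield an
#' `ND` record rather than an error. Ties across categories are broken by
#' the category order of the map and flagged.
#'
#' @param genes Character vector of gene symbols to score.
#' @param atlas Atlas tibble: `symbol` column plus one numeric column per
#'   cell type.
#' @param category_map Tibble with `cell_type` and `category` columns
#'   covering every atlas cell type.
#' @param synonym_map Optional synonym tibble (`old`, `current`) applied to
#'   `genes` before lookup (see [update_symbols()]).
#' @param directions Optional tibble (`symbol`, `direction`) merged into
#'   the result, e.g. DE directions.
#' @param zero_sub Zero replacement passed to [specificity_score()].
#' @return Tibble of class `cortseq_specificity`: `symbol`,
#'   `best_category`, `score`, `bin` (`"[1,2)"`, `"[2,3)"`, `">=3"`,
#'   `"<1"`, or `"ND"`), `tie`, and `direction` when supplied.
#' @export
score_specificity <- function(genes, atlas, category_map, synonym_map = NULL,
                              directions = NULL, zero_sub = 1e-4) {
  if (nrow(category_map) == 0) abort("`category_map` is empty.")
  if (!"symbol" %in% names(atlas)) abort("`atlas` must have a `symbol` column.")
  cats <- unique(category_map$category)
  lookup <- as.character(genes)
  if (!is.null(synonym_map)) {
    lookup <- update_symbols(lookup, synonym_map)$updated
  }
  amat <- as.matrix(atlas[setdiff(names(atlas), "symbol")])
  rownames(amat) <- atlas$symbol
  unmapped <- setdiff(colnames(amat), category_map$cell_type)
  if (length(unmapped) > 0) {
    abort(sprintf("Atlas cell type(s) missing from category map: %s.",
                  paste(utils::head(unmapped, 5L), collapse = ", ")))
  }

  rows <- purrr::map2_dfr(genes, lookup, function(orig, sym) {
    if (!sym %in% rownames(amat)) {
      return(tibble(symbol = orig, best_category = NA_character_,
                    score = NA_real_, bin = "ND", tie = FALSE))
    }
    expr <- amat[sym, ]
    scores <- vapply(cats, function(cc) {
      specificity_score(expr, cc, category_map, zero_sub = zero_sub)
    }, numeric(1))
    best <- which.max(scores)  # first maximum = map order tie-break
    tie <- sum(abs(scores - scores[best]) <= 1e-12 * max(scores[best], 1)) > 1
    tibble(symbol = orig, best_category = cats[best],
           score = unname(scores[best]), bin = score_bin(scores[best]),
           tie = tie)
  })
  if (!is.null(directions)) {
    rows <- dplyr::left_join(rows, directions, by = "symbol")
  }
  structure(rows, class = c("cortseq_specificity", class(rows)))
}

score_bin <- function(score) {
  dplyr::case_when(is.na(score) ~ "ND",
                   score < 1 ~ "<1",
                   score < 2 ~ "[1,2)",
                   score < 3 ~ "[2,3)",
                   TRUE ~ ">=3")
}

#' Bin fractions of specificity records
#'
#' Fractions of genes falling in the specificity bins `[1,2)`, `[2,3)`,
#' `>= 3` and `ND` (plus a `<1` sanity bin that stays empty when the
#' category map is total), and per-category counts of highly specific
#' (score >= 3) genes split by direction when directions are present.
#'
#' @param records A [score_specificity()] result.
#' @return List with `bins` (tibble: bin, n, fraction) and `by_category`
#'   (tibble of score >= 3 counts per best category and direction, or
#'   `NULL` when no direction column is present).
#' @export
specificity_bins <- function(records) {
  if (nrow(records) == 0) abort("`records` is empty.")
  lv <- c("<1", "[1,2)", "[2,3)", ">=3", "ND")
  bins <- records |>
    dplyr::count(bin = factor(.data$bin, levels = lv), .drop = FALSE,
                 name = "n") |>
    dplyr::mutate(fraction = .data$n / nrow(records))
  by_cat <- NULL
  if ("direction" %in% names(records)) {
    by_cat <- records |>
      dplyr::filter(.data$bin == ">=3") |>
      dplyr::count(.data$best_category, .data$direction, name = "n")
  }
  list(bins = bins, by_category = by_cat)
}
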