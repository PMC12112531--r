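# Internal helpers shared across modules.
#
# Convention used throughout the package: a "counts" (or CPM) table is a
# tibble whose first column, `gene_id`, holds unique gene identifiers and
# whose remaining columns are one numeric vector per sample. Sample metadata
# travels in a separate tibble keyed by `sample_id`.

#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
NULL

# Convert a counts/CPM tibble into a numeric matrix with gene_id rownames.
counts_matrix <- function(x, what = "counts") {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame with a gene_id first column.", what))
  }
  if (!"gene_id" %in% names(x)) {
    abort(sprintf("`%s` must contain a `gene_id` column.", what))
  }
  ids <- as.character(x$gene_id)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf(
      "Duplicated gene_id values in `%s`: %s.",
      what, paste(utils::head(dup, 5L), collapse = ", ")
    ))
  }
  m <- as.matrix(x[setdiff(names(x), "gene_id")])
  if (!is.numeric(m)) abort(sprintf("`%s` sample columns must be numeric.", what))
  rownames(m) <- ids
  m
}

# Matrix back to the tibble convention.
matrix_to_tibble <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(gene_id = rownames(m)), out)
}

check_metadata <- function(mat, metadata) {
  if (!is.data.frame(metadata) || !all(c("sample_id") %in% names(metadata))) {
    abort("`metadata` must be a data frame with a `sample_id` column.")
  }
  missing <- setdiff(colnames(mat), metadata$sample_id)
  if (length(missing) > 0) {
    abort(sprintf(
      "Samples missing from metadata: %s.",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  invisible(TRUE)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1].", name))
  }
  invisible(TRUE)
}

# Geometric mean of strictly positive values.
geomean <- function(x) exp(mean(log(x)))
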