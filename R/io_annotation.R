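# Reading/writing count tables and gene annotation, and the duplicate
# gene-symbol merging rule.

#' Read a gene-by-sample count matrix with its sample metadata
#'
#' Reads a tab-separated count table (first column `gene_id`, one column per
#' sample, integer counts) and a tab-separated metadata table keyed by
#' `sample_id`. The counts are validated: entries must be non-negative
#' integers, gene ids unique, and every sample column must be described in
#' the metadata.
#'
#' @param path Path to the count TSV.
#' @param metadata_path Path to the sample metadata TSV; must contain a
#'   `sample_id` column covering every sample column of the count table.
#' @return A list with elements `counts` (tibble, `gene_id` + one integer
#'   column per sample) and `metadata` (tibble).
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 50, seed = 1))
#' dir <- tempfile(); dir.create(dir)
#' write_counts(sim$counts, sim$metadata, file.path(dir, "counts.tsv"),
#'              file.path(dir, "meta.tsv"))
#' cm <- read_counts(file.path(dir, "counts.tsv"), file.path(dir, "meta.tsv"))
#' dim(cm$counts)
#' @export
read_counts <- function(path, metadata_path) {
  if (!file.exists(path)) abort(sprintf("Count file not found: %s", path))
  if (!file.exists(metadata_path)) {
    abort(sprintf("Metadata file not found: %s", metadata_path))
  }
  counts <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (!"gene_id" %in% names(counts)) {
    abort("Count table must have a `gene_id` first column.")
  }
  metadata <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                              progress = FALSE)
  mat <- counts_matrix(counts)
  if (any(!is.finite(mat))) abort("Count table contains missing values.")
  if (any(mat < 0)) {
    bad <- rownames(mat)[rowSums(mat < 0) > 0]
    abort(sprintf("Negative counts for gene(s): %s.",
                  paste(utils::head(bad, 5L), collapse = ", ")))
  }
  if (any(mat != round(mat))) {
    bad <- rownames(mat)[rowSums(mat != round(mat)) > 0]
    abort(sprintf("Non-integer counts for gene(s): %s.",
                  paste(utils::head(bad, 5L), collapse = ", ")))
  }
  check_metadata(mat, metadata)
  counts <- dplyr::mutate(counts, dplyr::across(-"gene_id", as.integer))
  list(counts = counts, metadata = metadata)
}

#' Write a count matrix and its metadata as TSV
#'
#' Plain tab-separated, UTF-8, unquoted output; gene ids in the first
#' column. The written pair round-trips through [read_counts()].
#'
#' @param counts Counts tibble (`gene_id` + sample columns).
#' @param metadata Sample metadata tibble.
#' @param path,metadata_path Output file paths.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(counts, metadata, path, metadata_path) {
  readr::write_tsv(counts, path, progress = FALSE)
  readr::write_tsv(metadata, metadata_path, progress = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Expects a TSV with columns `gene_id`, `symbol`, `biotype` and
#' `description`. A logical `is_predicted` column is derived from the
#' description: entries whose description contains the phrase
#' "predicted gene" (case-insensitive) are flagged as predicted genes.
#'
#' @param path Path to the annotation TSV.
#' @return Annotation tibble with the derived `is_predicted` column.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort(sprintf("Annotation file not found: %s", path))
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_annotation(ann)
}

#' Validate (and complete) a gene annotation table
#'
#' @param ann Data frame with at least `gene_id`, `symbol` and `biotype`
#'   columns; `description` is optional (defaults to empty).
#' @return A tibble with columns `gene_id`, `symbol`, `biotype`,
#'   `description`, `is_predicted`.
#' @export
validate_annotation <- function(ann) {
  need <- c("gene_id", "symbol", "biotype")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0) {
    abort(sprintf("Annotation is missing column(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  ann <- as_tibble(ann)
  if (anyDuplicated(ann$gene_id)) abort("Annotation gene_id values must be unique.")
  if (any(is.na(ann$symbol) | ann$symbol == "")) {
    abort("Annotation symbols must be non-empty.")
  }
  if (!"description" %in% names(ann)) ann$description <- ""
  ann$is_predicted <- stringr::str_detect(
    tolower(dplyr::coalesce(ann$description, "")), stringr::fixed("predicted gene")
  )
  ann
}

#' Merge duplicate gene symbols with matching biotypes
#'
#' Gene symbols mapped to more than one gene id are collapsed to a single
#' entry with per-sample summed counts, but only when the duplicated entries
#' share the same biotype; symbols whose copies carry different biotypes
#' (e.g. a protein-coding gene alongside a processed pseudogene) are left as
#' separate entries. The surviving key of a merged entry is the
#' lexicographically smallest gene id; the merge report lists all collapsed
#' ids per entry.
#'
#' @param counts Counts tibble (`gene_id` + sample columns).
#' @param annotation Annotation tibble covering every gene id in `counts`
#'   (see [validate_annotation()]).
#' @return List with `counts` (merged), `annotation` (merged, one row per
#'   surviving entry) and `report` (tibble: `symbol`, `biotype`, `gene_id`
#'   kept, `merged_ids` comma-separated, `n_merged`).
#' @examples
#' counts <- tibble::tibble(gene_id = c("G1", "G2"), s1 = c(3L, 5L), s2 = c(4L, 6L))
#' ann <- tibble::tibble(gene_id = c("G1", "G2"), symbol = "Bfar",
#'                       biotype = "protein_coding", description = "")
#' merge_duplicate_symbols(counts, ann)$counts
#' @export
merge_duplicate_symbols <- function(counts, annotation) {
  annotation <- validate_annotation(annotation)
  mat <- counts_matrix(counts)
  missing <- setdiff(rownames(mat), annotation$gene_id)
  if (length(missing) > 0) {
    abort(sprintf("Gene id(s) absent from annotation: %s.",
                  paste(utils::head(missing, 5L), collapse = ", ")))
  }
  ann <- annotation[match(rownames(mat), annotation$gene_id), ]

  key <- paste(ann$symbol, ann$biotype, sep = "\r")
  groups <- split(seq_len(nrow(mat)), key)
  multi <- groups[lengths(groups) > 1L]

  keep_rows <- mat
  report <- tibble(symbol = character(), biotype = character(),
                   gene_id = character(), merged_ids = character(),
                   n_merged = integer())
  drop <- integer(0)
  for (idx in multi) {
    ids <- sort(rownames(mat)[idx])
    primary <- ids[1L]
    pos <- match(primary, rownames(mat))
    keep_rows[pos, ] <- colSums(mat[idx, , drop = FALSE])
    drop <- c(drop, setdiff(idx, pos))
    report <- dplyr::bind_rows(report, tibble(
      symbol = ann$symbol[pos], biotype = ann$biotype[pos],
      gene_id = primary, merged_ids = paste(ids, collapse = ","),
      n_merged = length(ids)
    ))
  }
  if (length(drop) > 0) {
    keep_rows <- keep_rows[-drop, , drop = FALSE]
    ann <- ann[-drop, ]
  }
  storage <- matrix_to_tibble(keep_rows)
  storage <- dplyr::mutate(storage, dplyr::across(-"gene_id", as.integer))
  list(counts = storage, annotation = as_tibble(ann), report = report)
}
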