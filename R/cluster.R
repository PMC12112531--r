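# Gene clustering stage: per-gene max-ratio transform, complete-linkage
# hierarchical clustering with uncentered correlation, Cluster 3.0
# compatible CDT/GTR output, and node-correlation summaries.

#' Max-ratio transform
#'
#' Divides each gene's values by the gene's maximum so every row lies in
#' `[0, 1]` with its peak at exactly 1 -- the transform used to put genes
#' with wildly different absolute expression on a common visual scale
#' before clustering. All-zero rows are left as zeros and flagged.
#'
#' @param cpm CPM tibble (`gene_id` + sample columns), values >= 0.
#' @return Transformed tibble; attribute `zero_rows` lists all-zero genes.
#' @examples
#' max_ratio_transform(tibble::tibble(gene_id = "g", a = 2, b = 4, c = 8))
#' @export
max_ratio_transform <- function(cpm) {
  mat <- counts_matrix(cpm, "cpm")
  if (any(mat < 0)) abort("Max-ratio transform requires non-negative values.")
  mx <- apply(mat, 1, max)
  zero <- mx == 0
  mx[zero] <- 1
  out <- matrix_to_tibble(mat / mx)
  attr(out, "zero_rows") <- rownames(mat)[zero]
  out
}

#' Uncentered correlation
#'
#' `sum(x*y) / sqrt(sum(x^2) * sum(y^2))` -- correlation about zero rather
#' than about the mean (the Cluster 3.0 similarity metric, equal weights).
#'
#' @param x,y Numeric vectors of equal length; neither may be all-zero.
#' @return Similarity in `[-1, 1]`.
#' @examples
#' uncentered_correlation(c(1, 0), c(0, 1))
#' @export
uncentered_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1) {
    abort("`x` and `y` must be equal-length, non-empty vectors.")
  }
  sx <- sum(x^2); sy <- sum(y^2)
  if (sx == 0 || sy == 0) {
    abort("Uncentered correlation is undefined for an all-zero vector.")
  }
  sum(x * y) / sqrt(sx * sy)
}

# Pairwise uncentered-correlation similarity matrix over rows.
uncentered_similarity <- function(mat) {
  norms <- sqrt(rowSums(mat^2))
  if (any(norms == 0)) {
    bad <- rownames(mat)[norms == 0]
    abort(sprintf("All-zero row(s) make similarity undefined: %s.",
                  paste(utils::head(bad, 5L), collapse = ", ")))
  }
  s <- tcrossprod(mat / norms)
  s[s > 1] <- 1; s[s < -1] <- -1
  s
}

#' Complete-linkage hierarchical clustering with uncentered correlation
#'
#' Clusters genes (rows) agglomeratively with distance
#' `1 - uncentered correlation` and complete linkage: the distance between
#' two clusters is the largest pairwise distance between their members, so
#' node similarities are non-increasing from the leaves toward the root.
#'
#' @param x Transformed tibble (from [max_ratio_transform()]) or any
#'   gene-by-sample tibble/matrix with at least two genes.
#' @return A `cortseq_clust` object: `merge` (hclust-style merge matrix),
#'   `similarity` (per internal node, `1 - merge height`), `labels` (gene
#'   ids), `order` (leaf order), and the underlying `hclust` fit.
#' @export
hcluster_complete <- function(x) {
  mat <- if (is.matrix(x)) x else counts_matrix(x, "matrix")
  if (nrow(mat) < 2) abort("Clustering needs at least two genes.")
  s <- uncentered_similarity(mat)
  d <- stats::as.dist(1 - s)
  hc <- stats::hclust(d, method = "complete")
  hc$labels <- rownames(mat)
  structure(list(merge = hc$merge, similarity = 1 - hc$height,
                 labels = rownames(mat), order = hc$order, hclust = hc),
            class = "cortseq_clust")
}

#' @export
print.cortseq_clust <- function(x, ...) {
  cat(sprintf("Complete-linkage gene tree: %d leaves, %d internal nodes\n",
              length(x$labels), nrow(x$merge)))
  cat(sprintf("  node similarities (uncentered r): %.3f .. %.3f\n",
              min(x$similarity), max(x$similarity)))
  invisible(x)
}

# Leaves (label indices) under hclust-style node k of a merge matrix.
merge_leaves <- function(merge, k) {
  stack <- k; leaves <- integer(0)
  while (length(stack) > 0) {
    node <- stack[[1]]; stack <- stack[-1]
    for (child in merge[node, ]) {
      if (child < 0) leaves <- c(leaves, -child) else stack <- c(stack, child)
    }
  }
  leaves
}

#' Write Cluster 3.0 compatible CDT and GTR files
#'
#' The CDT holds the (transformed) data table with `GID`, `ORF`, `NAME`
#' and `GWEIGHT` columns, an `EWEIGHT` row, and rows in dendrogram leaf
#' order; the GTR lists one line per internal node
#' (`NODEkX child1 child2 similarity`, children being `GENEiX` or
#' `NODEjX`). The pair loads in Java TreeView.
#'
#' @param x Gene-by-sample tibble/matrix the tree was built on.
#' @param tree A [hcluster_complete()] result over the same genes.
#' @param out_prefix Output path prefix; writes `<prefix>.cdt` and
#'   `<prefix>.gtr`.
#' @param annotation Optional annotation tibble supplying gene `NAME`s
#'   (symbols); defaults to the gene ids.
#' @return Invisibly, the two file paths.
#' @export
write_cdt_gtr <- function(x, tree, out_prefix, annotation = NULL) {
  mat <- if (is.matrix(x)) x else counts_matrix(x, "matrix")
  if (!identical(rownames(mat), tree$labels)) {
    abort("`tree` was not built on the genes of `x` (labels differ).")
  }
  n <- nrow(mat)
  gid <- sprintf("GENE%dX", seq_len(n) - 1L)
  name <- rownames(mat)
  if (!is.null(annotation)) {
    ann <- validate_annotation(annotation)
    hit <- match(rownames(mat), ann$gene_id)
    name <- ifelse(is.na(hit), rownames(mat), ann$symbol[hit])
  }

  cdt_path <- paste0(out_prefix, ".cdt")
  gtr_path <- paste0(out_prefix, ".gtr")

  header <- paste(c("GID", "ORF", "NAME", "GWEIGHT", colnames(mat)),
                  collapse = "\t")
  eweight <- paste(c("EWEIGHT", "", "", "", rep("1", ncol(mat))),
                   collapse = "\t")
  ord <- tree$order
  body <- vapply(ord, function(i) {
    paste(c(gid[i], rownames(mat)[i], name[i], "1",
            format(mat[i, ], digits = 10, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, eweight, body), cdt_path)

  node_id <- function(v) {
    ifelse(v < 0, sprintf("GENE%dX", -v - 1L), sprintf("NODE%dX", v))
  }
  gtr <- vapply(seq_len(nrow(tree$merge)), function(k) {
    paste(c(sprintf("NODE%dX", k), node_id(tree$merge[k, 1]),
            node_id(tree$merge[k, 2]),
            format(tree$similarity[k], digits = 10, trim = TRUE,
                   scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(gtr, gtr_path)
  invisible(c(cdt = cdt_path, gtr = gtr_path))
}

#' Read a CDT file written by [write_cdt_gtr()]
#' @param path CDT path.
#' @return Tibble: `gene_id` + sample columns, rows in stored (leaf) order.
#' @export
read_cdt <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  samples <- header[-(1:4)]
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  ids <- vapply(body, `[[`, character(1), 2L)
  vals <- t(vapply(body, function(f) as.numeric(f[-(1:4)]),
                   numeric(length(samples))))
  colnames(vals) <- samples
  dplyr::bind_cols(tibble(gene_id = ids), as_tibble(vals, .name_repair = "minimal"))
}

#' Read a GTR file written by [write_cdt_gtr()]
#' @param path GTR path.
#' @return Tibble: `node`, `child1`, `child2`, `similarity`.
#' @export
read_gtr <- function(path) {
  body <- strsplit(readLines(path), "\t", fixed = TRUE)
  tibble(
    node = vapply(body, `[[`, character(1), 1L),
    child1 = vapply(body, `[[`, character(1), 2L),
    child2 = vapply(body, `[[`, character(1), 3L),
    similarity = vapply(body, function(f) as.numeric(f[4]), numeric(1))
  )
}

#' Joining-node similarity summary for a gene subset
#'
#' For each gene of the subset, walks from its leaf toward the root and
#' records the similarity of the first (and therefore highest-similarity)
#' internal node whose other branch contains at least one other subset
#' gene -- the node at which the gene joins the subset's subtree. Reports
#' the fraction of subset genes whose joining similarity reaches the
#' threshold. A singleton subset falls back to the gene's first merge node.
#'
#' @param tree A [hcluster_complete()] result.
#' @param genes Character vector of gene ids (subset of the tree leaves).
#' @param threshold Similarity threshold (e.g. 0.8).
#' @return List: `per_gene` (tibble gene_id, join_similarity), `fraction`
#'   of subset genes at or above `threshold`, and `threshold`.
#' @export
node_correlation_summary <- function(tree, genes, threshold = 0.8) {
  if (length(genes) == 0) abort("`genes` must be non-empty.")
  missing <- setdiff(genes, tree$labels)
  if (length(missing) > 0) {
    abort(sprintf("Gene(s) not in tree: %s.",
                  paste(utils::head(missing, 5L), collapse = ", ")))
  }
  merge <- tree$merge
  n_nodes <- nrow(merge)
  # parent pointer for every leaf (-i) and node (k)
  parent_of_leaf <- integer(length(tree$labels))
  parent_of_node <- integer(n_nodes)
  for (k in seq_len(n_nodes)) {
    for (child in merge[k, ]) {
      if (child < 0) parent_of_leaf[-child] <- k else parent_of_node[child] <- k
    }
  }
  leaf_sets <- lapply(seq_len(n_nodes), function(k) merge_leaves(merge, k))
  subset_idx <- match(genes, tree$labels)
  in_subset <- logical(length(tree$labels))
  in_subset[subset_idx] <- TRUE

  join_sim <- vapply(subset_idx, function(i) {
    node <- parent_of_leaf[i]
    prev <- -i
    while (node != 0) {
      sib <- setdiff(merge[node, ], prev)
      sib_leaves <- if (sib < 0) -sib else leaf_sets[[sib]]
      other <- setdiff(sib_leaves, i)
      if (length(genes) == 1 || any(in_subset[other])) {
        return(tree$similarity[node])
      }
      prev <- node
      node <- parent_of_node[node]
    }
    NA_real_
  }, numeric(1))

  per_gene <- tibble(gene_id = tree$labels[subset_idx],
                     join_similarity = join_sim)
  list(per_gene = per_gene,
       fraction = mean(join_sim >= threshold, na.rm = TRUE),
       threshold = threshold)
}
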