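# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results by brute force (exhaustive
# enumeration, O(n^3) agglomeration, direct arithmetic) so the package
# implementations are checked against code that shares none of their
# internals.

# --- fixtures -------------------------------------------------------------

# tibble convention -> plain matrix
as_mat <- function(tb) {
  m <- as.matrix(tb[setdiff(names(tb), "gene_id")])
  rownames(m) <- tb$gene_id
  m
}

toy_counts <- function(mat, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(mat)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(mat)))
  colnames(mat) <- samples
  dplyr::bind_cols(tibble::tibble(gene_id = genes),
                   tibble::as_tibble(mat, .name_repair = "minimal"))
}

toy_annotation <- function(gene_ids, symbols = gene_ids,
                           biotype = "protein_coding", description = "") {
  tibble::tibble(gene_id = gene_ids, symbol = symbols,
                 biotype = biotype, description = description)
}

# Two-group NB count tibble with given per-group means (vectors over genes).
nb_two_group <- function(mean1, mean2, n1 = 8, n2 = 8, phi = 0.1, seed = 1) {
  set.seed(seed)
  ng <- length(mean1)
  m <- cbind(
    matrix(rnbinom(ng * n1, size = 1 / phi, mu = rep(mean1, n1)), ng, n1),
    matrix(rnbinom(ng * n2, size = 1 / phi, mu = rep(mean2, n2)), ng, n2)
  )
  list(counts = toy_counts(m),
       groups = rep(c("A", "B"), c(n1, n2)))
}

# --- Mann-Whitney exhaustive enumeration ---------------------------------

bf_mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u1_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, u_of)
  lower <- mean(u_all <= u1_obs)
  upper <- mean(u_all >= u1_obs)
  list(U = min(u1_obs, n1 * n2 - u1_obs),
       p = min(1, 2 * min(lower, upper)))
}

# --- complete-linkage brute-force agglomerator ---------------------------

bf_uncentered_dist <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- 1 - sum(mat[i, ] * mat[j, ]) /
      sqrt(sum(mat[i, ]^2) * sum(mat[j, ]^2))
  }
  d
}

# Agglomerates with complete linkage, recomputing every cluster-pair
# distance from scratch at each step. Returns the set of formed clusters
# (sorted leaf indices) with their merge heights, which identifies the
# tree irrespective of merge bookkeeping.
bf_complete_linkage <- function(mat) {
  d <- bf_uncentered_dist(mat)
  clusters <- as.list(seq_len(nrow(mat)))
  out <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dij <- max(d[clusters[[i]], clusters[[j]]])
      if (dij < best_d - 1e-15) {
        best_d <- dij; best <- c(i, j)
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    out[[length(out) + 1]] <- list(leaves = merged, height = best_d)
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  out
}

# Canonical form of a tree for comparison: sorted "leafset@height" strings.
tree_signature <- function(clusters) {
  sort(vapply(clusters, function(cl) {
    sprintf("%s@%.8f", paste(cl$leaves, collapse = ","), cl$height)
  }, character(1)))
}

clust_signature <- function(fit) {
  clusters <- lapply(seq_len(nrow(fit$merge)), function(k) {
    leaves <- cortseq:::merge_leaves(fit$merge, k)
    list(leaves = sort(leaves), height = 1 - fit$similarity[k])
  })
  tree_signature(clusters)
}

# --- TMM step-by-step oracle ---------------------------------------------

bf_tmm_factor <- function(y, yr, n, nr, trim_m = 0.3, trim_a = 0.05) {
  ok <- y > 0 & yr > 0
  y <- y[ok]; yr <- yr[ok]
  m <- log2((y / n) / (yr / nr))
  a <- 0.5 * log2((y / n) * (yr / nr))
  w <- (n - y) / (n * y) + (nr - yr) / (nr * yr)
  keep <- rep(TRUE, length(m))
  lo_m <- floor(length(m) * trim_m); lo_a <- floor(length(a) * trim_a)
  rm_ <- rank(m); ra_ <- rank(a)
  keep <- rm_ > lo_m & rm_ <= length(m) - lo_m &
    ra_ > lo_a & ra_ <= length(a) - lo_a
  2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
}
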