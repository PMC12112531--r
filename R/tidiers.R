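# broom-style tidiers and ggplot2 plotting methods for the package's
# result classes.

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a DE result
#' @param x A `cortseq_de` tibble.
#' @param ... Unused.
#' @return The underlying tibble, one row per gene.
#' @method tidy cortseq_de
#' @export
tidy.cortseq_de <- function(x, ...) as_tibble(x)

#' One-row summary of a DE result
#' @param x A `cortseq_de` tibble.
#' @param alpha Significance cut-off on adjusted p (default 0.05).
#' @param ... Unused.
#' @return Tibble: comparison, n_genes, n_significant, n_up, n_down,
#'   dispersion.
#' @method glance cortseq_de
#' @export
glance.cortseq_de <- function(x, alpha = 0.05, ...) {
  sig <- dplyr::filter(as_tibble(x), .data$adj_pvalue < alpha)
  tibble(
    comparison = x$comparison[1],
    n_genes = nrow(x),
    n_significant = nrow(sig),
    n_up = sum(sig$direction == "up"),
    n_down = sum(sig$direction == "down"),
    dispersion = attr(x, "dispersion") %||% NA_real_
  )
}

#' Volcano plot of a DE result
#' @param object A `cortseq_de` tibble.
#' @param alpha Significance cut-off (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cortseq_de
#' @export
autoplot.cortseq_de <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(object) |>
    dplyr::mutate(status = dplyr::case_when(
      .data$adj_pvalue < alpha & .data$logFC > 0 ~ "up",
      .data$adj_pvalue < alpha & .data$logFC < 0 ~ "down",
      TRUE ~ "ns"))
  ggplot2::ggplot(df, ggplot2::aes(.data$logFC, -log10(.data$pvalue),
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2471a3",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = df$comparison[1]) +
    ggplot2::theme_minimal()
}

#' Tidy a gene cluster tree
#' @param x A `cortseq_clust` object.
#' @param ... Unused.
#' @return Tibble with one row per internal node: node, child1, child2,
#'   similarity, height.
#' @method tidy cortseq_clust
#' @export
tidy.cortseq_clust <- function(x, ...) {
  id <- function(v) vapply(v, function(vi) {
    if (vi < 0) x$labels[-vi] else paste0("node_", vi)
  }, character(1))
  tibble(node = paste0("node_", seq_len(nrow(x$merge))),
         child1 = id(x$merge[, 1]), child2 = id(x$merge[, 2]),
         similarity = x$similarity, height = 1 - x$similarity)
}

#' One-row summary of a cluster tree
#' @param x A `cortseq_clust` object.
#' @param ... Unused.
#' @return Tibble: n_leaves, n_nodes, min/max node similarity.
#' @method glance cortseq_clust
#' @export
glance.cortseq_clust <- function(x, ...) {
  tibble(n_leaves = length(x$labels), n_nodes = nrow(x$merge),
         min_similarity = min(x$similarity),
         max_similarity = max(x$similarity))
}

#' Dendrogram of a gene cluster tree
#' @param object A `cortseq_clust` object.
#' @param ... Unused.
#' @return A ggplot object drawing the dendrogram with the similarity axis.
#' @method autoplot cortseq_clust
#' @export
autoplot.cortseq_clust <- function(object, ...) {
  merge <- object$merge
  n <- length(object$labels)
  leaf_x <- integer(n); leaf_x[object$order] <- seq_len(n)
  node_x <- numeric(nrow(merge)); node_h <- 1 - object$similarity
  seg <- purrr::map_dfr(seq_len(nrow(merge)), function(k) {
    pos <- vapply(merge[k, ], function(v) {
      if (v < 0) leaf_x[-v] else node_x[v]
    }, numeric(1))
    hts <- vapply(merge[k, ], function(v) {
      if (v < 0) 0 else node_h[v]
    }, numeric(1))
    node_x[k] <<- mean(pos)
    tibble(x = c(pos[1], pos[2], pos[1]), xend = c(pos[1], pos[2], pos[2]),
           y = c(hts[1], hts[2], node_h[k]), yend = rep(node_h[k], 3))
  })
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = seq_len(n),
                                labels = object$labels[object$order]) +
    ggplot2::labs(x = NULL, y = "1 - uncentered correlation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Bar chart of the expression-tier summary
#' @param summary A [tier_summary()] tibble.
#' @param what `"genes"` or `"transcripts"` -- which percentage to draw.
#' @return A ggplot object.
#' @export
plot_tier_summary <- function(summary, what = c("genes", "transcripts")) {
  what <- match.arg(what)
  col <- if (what == "genes") "pct_genes" else "pct_transcripts"
  ggplot2::ggplot(summary, ggplot2::aes(.data$tier, .data[[col]])) +
    ggplot2::geom_col(fill = "#34495e") +
    ggplot2::labs(x = "expression tier (CPM decades)",
                  y = sprintf("%% of %s", what)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of |log2FC| against expression level
#' @param de A DE tibble.
#' @param alpha Significance cut-off selecting plotted genes.
#' @return A ggplot object with a linear trend line.
#' @export
plot_fc_vs_expression <- function(de, alpha = 0.05) {
  sig <- dplyr::filter(as_tibble(de), .data$adj_pvalue < alpha)
  ggplot2::ggplot(sig, ggplot2::aes(.data$log10_mean_cpm, abs(.data$logFC))) +
    ggplot2::geom_point(size = 0.7, alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#c0392b") +
    ggplot2::labs(x = "log10 mean CPM", y = "|log2 fold change|") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
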