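#' Plot a clonal phylogeny
#'
#' Simple top-down layout: depth on the vertical axis, leaves spread
#' horizontally, node size proportional to the mutation count.
#'
#' @param object A [clone_tree()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot clone_tree
#' @export
autoplot.clone_tree <- function(object, ...) {
  depth <- node_depths(object)
  ord <- order(depth, object$clone_id)
  x <- numeric(nrow(object))
  leaves <- leaf_depths(object)$clone_id
  x[match(leaves, object$clone_id)] <- seq_along(leaves)
  # internal nodes sit at the mean of their children's x
  for (i in rev(ord)) {
    kids <- which(object$parent_id == object$clone_id[i])
    if (length(kids) > 0) x[i] <- mean(x[kids])
  }
  df <- tibble::tibble(
    clone_id = object$clone_id, x = x, y = -depth,
    n_mutations = object$n_mutations,
    parent = match(object$parent_id, object$clone_id)
  )
  edges <- df[!is.na(df$parent), ]
  edges$xend <- df$x[edges$parent]
  edges$yend <- df$y[edges$parent]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_mutations)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$clone_id), vjust = -1) +
    ggplot2::labs(x = NULL, y = "depth (edges below root)",
                  title = sprintf("Tree score %.3f", tree_score(object))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Heatmap of mean clone counts over the burden plane
#'
#' Renders [clone_heatmap()] bins as tiles: normalized log CNA burden on x,
#' normalized log mutation burden on y, fill by mean clone count. The most
#' heterogeneous samples are expected toward the top-right (high in both).
#'
#' @param heatmap A tibble from [clone_heatmap()].
#' @return A ggplot.
#' @export
plot_clone_heatmap <- function(heatmap) {
  ggplot2::ggplot(heatmap, ggplot2::aes(x = .data$x_mid, y = .data$y_mid,
                                        fill = .data$mean_clones)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(option = "plasma") +
    ggplot2::labs(x = "normalized log(1 + CNA segments)",
                  y = "normalized log(1 + mutations)",
                  fill = "mean clones") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Tree score against clone count
#'
#' Scatter of per-sample (or per-simulation) Tree scores versus clone
#' counts, with the attainable envelope: linear phylogenies sit at 0 and
#' the star tree bounds the score at `1 - 1/(N-1)`.
#'
#' @param data Tibble with columns `n_clones` and `tree_score`.
#' @return A ggplot.
#' @export
plot_tree_score <- function(data) {
  stopifnot(all(c("n_clones", "tree_score") %in% names(data)))
  nmax <- max(data$n_clones, na.rm = TRUE)
  env <- tibble::tibble(n_clones = 2:max(3, nmax))
  env$upper <- 1 - 1 / (env$n_clones - 1)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$n_clones, y = .data$tree_score)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.5) +
    ggplot2::geom_line(data = env, ggplot2::aes(y = .data$upper),
                       color = "red", linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, color = "darkgreen", linetype = 2) +
    ggplot2::labs(x = "number of clones", y = "Tree score") +
    ggplot2::theme_minimal()
}

#' Clonal versus subclonal enrichment scores
#'
#' Scatter of `-log10 p` for the clonal (x) and subclonal (y) tests, one
#' point per feature and tumor type, colored by enrichment class, with the
#' score threshold drawn on both axes.
#'
#' @param enrichment A tibble from [enrichment_scan()].
#' @param score_threshold Threshold line to draw (default 2.5).
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrichment, score_threshold = 2.5) {
  ok <- enrichment[!enrichment$skipped, ]
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$score_clonal,
                                   y = .data$score_subclonal,
                                   color = .data$enrichment_class)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = score_threshold, linetype = 2) +
    ggplot2::geom_vline(xintercept = score_threshold, linetype = 2) +
    ggplot2::labs(x = "clonal score (-log10 p)",
                  y = "subclonal score (-log10 p)", color = "class") +
    ggplot2::theme_minimal()
}
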