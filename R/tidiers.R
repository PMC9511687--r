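#' @export
tidy.alp_communities <- function(x, ...) {
  tibble(node = names(x$membership), community = as.integer(x$membership))
}

#' @export
glance.alp_communities <- function(x, ...) {
  tibble(n_nodes = length(x$membership),
         n_communities = dplyr::n_distinct(x$membership),
         modularity = x$modularity)
}

#' @export
tidy.alp_heatmap <- function(x, ...) {
  as_tibble(x$matrix, rownames = "cluster") |>
    tidyr::pivot_longer(-"cluster", names_to = "term", values_to = "score") |>
    mutate(row_group = unname(x$row_groups[.data$cluster]),
           col_group = unname(x$col_groups[.data$term]))
}

#' @export
tidy.ldp_network <- function(x, ...) {
  at <- igraph::vertex_attr(x)
  as_tibble(at) |> rename(node = "name")
}

#' Heatmap of -log10(FDR) enrichment scores with k-means groups
#'
#' Rows (clusters) and columns (terms) are ordered by their k-means group;
#' dashed lines mark the group boundaries, mirroring the usual
#' supercluster/group presentation of community-level GO enrichment.
#'
#' @param object An [heatmap_matrix()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.alp_heatmap <- function(object, ...) {
  df <- tidy.alp_heatmap(object)
  row_ord <- names(sort(object$row_groups))
  col_ord <- names(sort(object$col_groups))
  df$cluster <- factor(df$cluster, levels = row_ord)
  df$term <- factor(df$term, levels = col_ord)
  hlines <- cumsum(rle(unname(sort(object$row_groups)))$lengths)
  vlines <- cumsum(rle(unname(sort(object$col_groups)))$lengths)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$cluster,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_hline(yintercept = utils::head(hlines, -1) + 0.5, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = utils::head(vlines, -1) + 0.5, linetype = "dashed") +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = expression(-log[10]~FDR)) +
    ggplot2::labs(x = "GO term", y = "Community") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1, vjust = 0.5))
}

#' Degree-betweenness quadrant scatter plot
#'
#' @param records Tibble from [classify_quadrants()].
#' @return A ggplot object with mean-degree and mean-betweenness reference
#'   lines separating the four quadrants.
#' @export
plot_quadrants <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$degree,
                                        y = .data$betweenness + 1,
                                        colour = .data$quadrant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = mean(records$degree), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = mean(records$betweenness) + 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Degree", y = "Betweenness + 1", colour = "Quadrant") +
    ggplot2::theme_minimal()
}

#' Pan-DEG meta-log2FC by category
#'
#' @param pan_degs Tibble from [pan_deg_intersect()].
#' @return A ggplot box/jitter plot of meta-log2FC per functional category.
#' @export
plot_pan_degs <- function(pan_degs) {
  ggplot2::ggplot(pan_degs, ggplot2::aes(x = .data$category,
                                         y = .data$meta_log2fc)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = expression(meta-log[2]~FC)) +
    ggplot2::theme_minimal()
}
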