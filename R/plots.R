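#' Plot a repeat landscape
#'
#' Stacked abundance per 1-percent Kimura-divergence bin, one fill per
#' family: recent amplifications pile up near 0% divergence.
#'
#' @param landscape A `sat_landscape` tibble from [repeat_landscape()].
#' @return A ggplot object.
#' @export
plot_landscape <- function(landscape) {
  ggplot2::ggplot(landscape,
                  ggplot2::aes(x = .data$bin, y = .data$abundance,
                               fill = .data$family)) +
    ggplot2::geom_col(width = 0.95) +
    ggplot2::labs(x = "Kimura 2-parameter divergence (%)",
                  y = "Genome proportion (%)", fill = "Family") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_landscape
#' @param object A `sat_landscape`.
#' @param ... Unused.
#' @export
autoplot.sat_landscape <- function(object, ...) {
  plot_landscape(object)
}

#' Plot a minimum spanning tree of satellite variants
#'
#' Nodes are variants; edge labels report substitutions (s) and indel
#' events (id) with the indel nucleotides in brackets.
#'
#' @param mst Edge tibble from [build_mst()].
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_mst <- function(mst, seed = 1) {
  g <- igraph::graph_from_data_frame(mst, directed = FALSE)
  lay <- with_seed(seed,
                   igraph::layout_with_fr(g,
                                          weights = igraph::E(g)$weight + 1))
  nodes <- tibble(name = igraph::V(g)$name,
                  x = lay[, 1], y = lay[, 2])
  edges <- as_tibble(igraph::as_data_frame(g, what = "edges"))
  edges <- left_join(edges, stats::setNames(nodes, c("from", "x1", "y1")),
                     by = "from")
  edges <- left_join(edges, stats::setNames(nodes, c("to", "x2", "y2")),
                     by = "to")
  edges$label <- sprintf("s=%d, id=%d [%d]", edges$s, edges$id, edges$id_nt)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x1, y = .data$y1,
                                       xend = .data$x2, yend = .data$y2),
                          colour = "grey50") +
    ggplot2::geom_label(data = edges,
                        ggplot2::aes(x = (.data$x1 + .data$x2) / 2,
                                     y = (.data$y1 + .data$y2) / 2,
                                     label = .data$label), size = 2.5) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$name),
                       vjust = -1) +
    ggplot2::theme_void()
}
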