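#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the instance graph of a store
#'
#' Draws the licensed instance graph (the edges along which operator
#' states migrate), nodes coloured by entity kind, using a
#' deterministic force-directed layout.
#'
#' @param object An `s3db_store`.
#' @param matrix Transition matrix selecting the drawn edges.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.s3db_store <- function(object, matrix = s3db_transition_matrix(),
                                ...) {
  edges <- instance_graph(object, matrix)
  nodes <- tidy.s3db_store(object)
  g <- igraph::graph_from_data_frame(
    edges, vertices = nodes["uri"], directed = TRUE)
  xy <- withr::with_seed(1, igraph::layout_with_fr(g))
  layout <- tibble::tibble(uri = igraph::V(g)$name,
                           x = xy[, 1], y = xy[, 2])
  nodes <- dplyr::left_join(nodes, layout, by = "uri")
  seg <- dplyr::left_join(edges, layout, by = c("from" = "uri"))
  seg <- dplyr::left_join(seg, layout, by = c("to" = "uri"),
                          suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey60",
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$kind),
      size = 3) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$local),
      vjust = -1, size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "kind")
}

#' Plot the effective states of a percolation pool
#'
#' A tile map of entity by operator, filled by the effective state
#' index (1 = most permissive); unassigned cells are blank.
#'
#' @param object An `s3db_pool`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.s3db_pool <- function(object, ...) {
  eff <- effective_states(object)
  ggplot2::ggplot(eff,
    ggplot2::aes(x = .data$operator, y = .data$entity,
                 fill = factor(.data$index))) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$symbol), size = 3) +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", direction = -1,
                               na.value = "grey90") +
    ggplot2::labs(fill = "state index") +
    ggplot2::theme_minimal()
}
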