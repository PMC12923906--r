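#' Plot a rate map
#'
#' Tile plot of the smoothed (if present) or raw firing-rate map, with
#' unvisited bins left blank.
#'
#' @param object A `ratemap_bundle`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ratemap_bundle <- function(object, ...) {
  rate <- if (!is.null(object$smoothed_rate)) object$smoothed_rate else
    object$raw_rate
  df <- dplyr::mutate(bin_centers(object$arena),
                      rate = rate[cbind(bin_x, bin_y)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90",
                                  name = "rate\n(events/s)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
}

#' Plot a functional network
#'
#' Force-directed layout with edge width proportional to the correlation
#' weight and nodes coloured by degree centrality.
#'
#' @param object A `functional_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.functional_network <- function(object, ...) {
  g <- object$graph
  set.seed(1)
  xy <- igraph::layout_with_fr(g)
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- object$edges
  if (nrow(edges)) {
    i <- match(edges$cell_i, nodes$cell_id)
    j <- match(edges$cell_j, nodes$cell_id)
    edges <- dplyr::mutate(edges, x = nodes$x[i], y = nodes$y[i],
                           xend = nodes$x[j], yend = nodes$y[j])
  }
  p <- ggplot2::ggplot()
  if (nrow(edges)) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$r),
      colour = "grey60", alpha = 0.6)
  }
  p + ggplot2::geom_point(
    data = nodes,
    ggplot2::aes(x = .data$x, y = .data$y, colour = .data$degree), size = 2) +
    ggplot2::scale_linewidth(range = c(0.2, 1.2), guide = "none") +
    ggplot2::scale_colour_viridis_c(name = "degree") +
    ggplot2::theme_void()
}

#' Plot the population signal with detected bursts
#'
#' @param popz Population z-score signal.
#' @param bursts Burst tibble from [detect_bursts()].
#' @param fps Frame rate.
#' @param z_threshold Threshold line to draw (default 2).
#' @return A ggplot object.
#' @export
plot_population_bursts <- function(popz, bursts, fps, z_threshold = 2) {
  df <- tibble::tibble(t = (seq_along(popz) - 1) / fps, z = popz)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$z)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = z_threshold, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "time (s)", y = "population z-score") +
    ggplot2::theme_minimal()
  if (nrow(bursts)) {
    p <- p + ggplot2::geom_rect(
      data = bursts, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$onset_s, xmax = .data$offset_s,
                   ymin = -Inf, ymax = Inf),
      fill = "red", alpha = 0.15)
  }
  p
}
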