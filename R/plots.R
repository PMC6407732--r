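#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Draw the hexagonal search array
#'
#' @param grid A [hex_grid()] object.
#' @param labels Draw cell ids at the centres.
#' @return A ggplot object.
#' @export
plot_search_array <- function(grid, labels = TRUE) {
  verts <- hex_vertices(grid)
  p <- ggplot2::ggplot(verts,
                       ggplot2::aes(x = .data$x_deg, y = .data$y_deg,
                                    group = .data$hex_id)) +
    ggplot2::geom_polygon(fill = NA, colour = "black") +
    ggplot2::coord_fixed() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)") +
    ggplot2::theme_minimal()
  if (labels) {
    p <- p + ggplot2::geom_text(
      data = hex_centers(grid),
      ggplot2::aes(label = .data$hex_id, group = NULL), size = 3,
      colour = "grey40"
    )
  }
  p
}

#' Overlay a scanpath on the search array
#'
#' @param fixations A fixation tibble (`onset`, `x`, `y`).
#' @param grid A [hex_grid()] object.
#' @param colour Path colour.
#' @return A ggplot object.
#' @export
plot_scanpath <- function(fixations, grid, colour = "firebrick") {
  plot_search_array(grid, labels = FALSE) +
    ggplot2::geom_path(
      data = fixations,
      ggplot2::aes(x = .data$x, y = .data$y, group = NULL),
      colour = colour, alpha = 0.7
    ) +
    ggplot2::geom_point(
      data = fixations,
      ggplot2::aes(x = .data$x, y = .data$y, group = NULL),
      colour = colour, size = 1.5
    )
}

#' @export
#' @method autoplot overlap_summary
autoplot.overlap_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (s)",
                  y = "cumulative overlap (proportion of cells)") +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot overlap_curve
autoplot.overlap_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data$value,
                               colour = .data$participant)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (s)",
                  y = "cumulative overlap (proportion of cells)") +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot gaze_heatmap
autoplot.gaze_heatmap <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)", fill = "density") +
    ggplot2::theme_minimal()
}
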