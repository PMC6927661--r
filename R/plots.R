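#' Plot a CPM configuration
#'
#' Tile map of the lattice, one fill per cell index (medium blank).
#'
#' @param object A [cpm_state()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cpm_state <- function(object, ...) {
  idx <- which(object$spin >= 0, arr.ind = TRUE)
  d <- tibble(x = as.numeric(idx[, 2]), y = as.numeric(idx[, 1]),
              cell = factor(object$spin[idx]))
  ggplot2::ggplot(dplyr::filter(d, .data$cell != "0"),
                  ggplot2::aes(.data$x, .data$y, fill = .data$cell)) +
    ggplot2::geom_tile(show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (sites)", y = "y (sites)") +
    ggplot2::theme_minimal()
}

#' Plot a force field
#'
#' Arrow map of a force table, optionally over the cell footprint.
#'
#' @param object A force table (from [boundary_forces()] and friends).
#' @param ... Unused.
#' @param arrow_scale Length multiplier applied to the vectors before
#'   drawing; default scales the largest arrow to ~3 sites.
#' @return A ggplot.
#' @export
autoplot.cpm_forces <- function(object, ..., arrow_scale = NULL) {
  mag <- sqrt(object$fx^2 + object$fy^2)
  if (is.null(arrow_scale)) {
    top <- max(mag, na.rm = TRUE)
    arrow_scale <- if (top > 0) 3 / top else 1
  }
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$x + .data$fx * arrow_scale,
                   yend = .data$y + .data$fy * arrow_scale,
                   colour = sqrt(.data$fx^2 + .data$fy^2)),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.1, "cm"))) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c(name = "|F|") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (sites)", y = "y (sites)") +
    ggplot2::theme_minimal()
}

#' Plot scenario summary series
#'
#' Per-cell area and perimeter over Monte Carlo steps.
#'
#' @param object A [run_scenario()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cpm_scenario <- function(object, ...) {
  d <- tidyr::pivot_longer(object$summary,
                           cols = c("area", "perimeter"),
                           names_to = "quantity", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$mcs, .data$value,
                                  group = interaction(.data$id, .data$quantity),
                                  colour = factor(.data$id))) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "MCS", y = NULL) +
    ggplot2::theme_minimal()
}

#' Overlay a force field on the cell configuration
#'
#' @param state A [cpm_state()].
#' @param forces A force table computed on it.
#' @param arrow_scale See [autoplot.cpm_forces()].
#' @return A ggplot.
#' @export
plot_force_field <- function(state, forces, arrow_scale = NULL) {
  base <- autoplot(state)
  mag <- sqrt(forces$fx^2 + forces$fy^2)
  if (is.null(arrow_scale)) {
    top <- max(mag, na.rm = TRUE)
    arrow_scale <- if (top > 0) 3 / top else 1
  }
  base +
    ggplot2::geom_segment(
      data = forces,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x + .data$fx * arrow_scale,
                   yend = .data$y + .data$fy * arrow_scale),
      inherit.aes = FALSE,
      arrow = ggplot2::arrow(length = ggplot2::unit(0.08, "cm")))
}
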