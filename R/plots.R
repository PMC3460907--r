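# ggplot2 displays for each result type.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an expression profile
#'
#' Per-channel mean intensity against A-P position; if a `signal` column is
#' present it is drawn on top.
#'
#' @param object An `expression_profile` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.expression_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              dplyr::any_of(c("red", "green", "blue", "signal")),
                              names_to = "channel", values_to = "intensity")
  cols <- c(red = "#c0392b", green = "#27ae60", blue = "#2980b9", signal = "black")
  ggplot2::ggplot(long, ggplot2::aes(.data$position, .data$intensity,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = cols) +
    ggplot2::labs(x = "A-P position (% egg length)", y = "mean intensity",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a boundary spline over its window
#'
#' @param object A `boundary_spline`.
#' @param n Evaluation points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.boundary_spline <- function(object, n = 100, ...) {
  xx <- seq(object$xs[1], object$xs[3], length.out = n)
  curve <- tibble(position = xx, intensity = eval_boundary(object, xx))
  ggplot2::ggplot(curve, ggplot2::aes(.data$position, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$knots,
                        ggplot2::aes(.data$x, .data$y), colour = "#c0392b") +
    ggplot2::labs(
      title = sprintf("%s slope %d (%s, %s)", object$gene, object$slope_id,
                      object$polarity, object$channel),
      x = "A-P position (% egg length)", y = "signal intensity") +
    ggplot2::theme_minimal()
}

#' Plot a variability dataset
#'
#' Individual boundary splines as thin lines and median splines as thick
#' ones, coloured by gene, one panel per time class.
#'
#' @param data Output of [variability_dataset()].
#' @return A ggplot.
#' @export
plot_variability <- function(data) {
  ggplot2::ggplot(data,
                  ggplot2::aes(.data$position, .data$intensity, colour = .data$gene,
                               group = interaction(.data$embryo_id, .data$gene,
                                                   .data$slope_id, .data$kind))) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$kind == "slope"),
                       linewidth = 0.3, alpha = 0.5) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$kind == "median"),
                       linewidth = 1.1) +
    ggplot2::facet_wrap(~time_class) +
    ggplot2::labs(x = "A-P position (% egg length)",
                  y = "normalised signal intensity", colour = "gene") +
    ggplot2::theme_minimal()
}

#' Space-time plot of median boundary mid-points
#'
#' A-P position on the x-axis, developmental time flowing downwards on the
#' y-axis.
#'
#' @param st Output of [spacetime_table()].
#' @return A ggplot.
#' @export
plot_spacetime <- function(st) {
  st$time_class <- time_class_factor(st$time_class)
  ggplot2::ggplot(st, ggplot2::aes(.data$x1_percent, .data$time_class,
                                   colour = .data$gene,
                                   group = interaction(.data$gene, .data$slope_id))) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "A-P position (% egg length)", y = "time class",
                  colour = "gene") +
    ggplot2::theme_minimal()
}

#' Display an embryo mask
#'
#' @param x An `embryo_mask`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.embryo_mask <- function(x, ...) {
  m <- t(x$mask[rev(seq_len(nrow(x$mask))), ])
  graphics::image(m, col = c("black", "white"), axes = FALSE, asp = nrow(x$mask) / ncol(x$mask), ...)
  invisible(x)
}
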