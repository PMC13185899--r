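# ggplot2 views of fits and requirement distributions. Every plotted
# quantity is also available as a tibble, so nothing downstream needs to
# parse a figure.

#' @describeIn fit_tanh_neuron Scatter of the data with the fitted tanh
#'   curve; pass a [curve_band()] tibble via `band` to shade the
#'   bootstrap envelope.
#' @param object a `tanh_fit`.
#' @param band optional tibble from [curve_band()].
#' @param n_grid points on the curve grid.
#' @param ... unused.
#' @method autoplot tanh_fit
#' @export
autoplot.tanh_fit <- function(object, band = NULL, n_grid = 200, ...) {
  grid <- seq(min(object$x), max(object$x), length.out = n_grid)
  curve <- tibble::tibble(x = grid,
                          y = predict_response(object$params, grid))
  pts <- tibble::tibble(x = object$x, y = object$y)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8)
  if (!is.null(band)) {
    p <- p + ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$x, ymin = .data$lower, ymax = .data$upper),
      inherit.aes = FALSE, alpha = 0.25
    )
  }
  p +
    ggplot2::geom_line(data = curve, colour = "#b2182b", linewidth = 0.9) +
    ggplot2::labs(x = object$nutrient, y = object$response) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_polynomial Scatter with the fitted line/parabola and
#'   its pointwise mean-response confidence band.
#' @param object a `poly_fit`.
#' @param level band level (default 0.95).
#' @param n_grid points on the grid.
#' @param ... unused.
#' @method autoplot poly_fit
#' @export
autoplot.poly_fit <- function(object, level = 0.95, n_grid = 200, ...) {
  grid <- seq(min(object$x), max(object$x), length.out = n_grid)
  band <- confidence_band(object, grid, level)
  pts <- tibble::tibble(x = object$x, y = object$y)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$x, ymin = .data$lower, ymax = .data$upper),
      inherit.aes = FALSE, alpha = 0.25
    ) +
    ggplot2::geom_line(
      data = band, ggplot2::aes(x = .data$x, y = .data$mean),
      colour = "#2166ac", linewidth = 0.9
    ) +
    ggplot2::labs(x = object$nutrient, y = object$response) +
    ggplot2::theme_minimal()
}

#' Notched boxplots of bootstrap requirement distributions
#'
#' One notched box per phase built from [boxplot_stats()] of the
#' replicate requirements, with the mean marked and compact letters
#' above the boxes.
#'
#' @param run a [run_pipeline()] result.
#' @param nutrient which nutrient to plot.
#' @return A ggplot object.
#' @export
plot_requirements <- function(run, nutrient = "me") {
  stopifnot(inherits(run, "phasereq_run"))
  stats <- run$boxplots[run$boxplots$nutrient == nutrient, ]
  if (nrow(stats) == 0) {
    abort(paste0("No results for nutrient ", nutrient),
          class = "phasereq_validation_error")
  }
  stats$phase <- factor(stats$phase, levels = phase_levels())
  lets <- run$letters[run$letters$nutrient == nutrient, ]
  stats <- dplyr::left_join(stats,
                            dplyr::select(lets, phase = "group", "letters"),
                            by = "phase")
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$phase)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$whisker_lo, ymax = .data$whisker_hi),
      width = 0.2
    ) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$median, ymin = .data$q1, ymax = .data$q3),
      fill = "grey85", width = 0.55
    ) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$median, ymin = .data$notch_lo,
                   ymax = .data$notch_hi),
      fill = "grey60", width = 0.3, linewidth = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean), shape = 8,
                        colour = "#b2182b", size = 2) +
    ggplot2::geom_text(ggplot2::aes(y = .data$whisker_hi,
                                    label = .data$letters),
                       vjust = -0.8) +
    ggplot2::labs(x = "production phase",
                  y = paste0("requirement (", nutrient, ")")) +
    ggplot2::theme_minimal()
}
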