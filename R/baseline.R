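# Linear and quadratic benchmark regressions with correlation, RMSE,
# term p-values and pointwise mean-response confidence bands.

#' Fit a linear or quadratic benchmark regression
#'
#' Ordinary least squares of the response on the nutrient intake
#' (degree 1) or on intake and intake squared (degree 2). Reports the
#' Pearson correlation `r` of x and y, `rmse = sqrt(SSE/n)` (the same
#' convention used for the tanh fit, so cross-model comparisons are
#' well defined), and two-sided t-test p-values per coefficient.
#'
#' @param data data frame; complete cases of the two columns are used.
#' @param nutrient,response column names.
#' @param degree 1 (linear) or 2 (quadratic).
#' @return An object of class `poly_fit` wrapping the `lm` fit with
#'   fields `degree`, `coefficients`, `term_p_values`, `r`, `rmse`,
#'   `n`, `residual_df`.
#' @export
#' @examples
#' d <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1)
#' glance(fit_polynomial(d, "x", "y", degree = 1))
fit_polynomial <- function(data, nutrient, response = "chicks_per_hen_week",
                           degree = 1) {
  if (!degree %in% c(1, 2)) {
    abort("`degree` must be 1 or 2.", class = "phasereq_validation_error")
  }
  ok <- stats::complete.cases(data[[nutrient]], data[[response]])
  x <- data[[nutrient]][ok]
  y <- data[[response]][ok]
  n <- length(x)
  if (n < degree + 2) {
    abort(sprintf("Need at least %d observations for degree %d.",
                  degree + 2, degree),
          class = "phasereq_size_error")
  }
  if (diff(range(x)) == 0) {
    abort("Nutrient intake is constant; the regression design is degenerate.",
          class = "phasereq_degenerate_error")
  }
  df <- data.frame(x = x, y = y)
  model <- if (degree == 1) {
    lm(y ~ x, data = df)
  } else {
    lm(y ~ x + I(x^2), data = df)
  }
  # suppressed: summary.lm warns on exact (zero-residual) fits
  sm <- suppressWarnings(summary(model))
  structure(
    list(model = model, degree = degree,
         coefficients = coef(model),
         term_p_values = sm$coefficients[, "Pr(>|t|)"],
         r = stats::cor(x, y),
         rmse = sqrt(mean(stats::residuals(model)^2)),
         n = n, residual_df = n - (degree + 1),
         nutrient = nutrient, response = response, x = x, y = y),
    class = "poly_fit"
  )
}

#' @export
print.poly_fit <- function(x, ...) {
  cat(sprintf("Degree-%d benchmark regression: n = %d, r = %.3f, RMSE = %.4g\n",
              x$degree, x$n, x$r, x$rmse))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.poly_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    p.value = unname(x$term_p_values)
  )
}

#' @export
glance.poly_fit <- function(x, ...) {
  tibble::tibble(degree = x$degree, n = x$n, r = x$r, rmse = x$rmse,
                 residual_df = x$residual_df)
}

#' @export
predict.poly_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) {
    object$x
  } else if (is.data.frame(newdata)) {
    newdata[[object$nutrient]] %||% newdata$x
  } else {
    newdata
  }
  unname(stats::predict(object$model, newdata = data.frame(x = x)))
}

#' Pointwise confidence band for the regression mean response
#'
#' t-based band for the predicted mean: half-width equals
#' `qt((1 + level)/2, residual_df)` times the standard error of the
#' fitted mean at each grid point. Grid points outside the observed
#' intake range are flagged as extrapolation.
#'
#' @param fit a [fit_polynomial()] result.
#' @param grid numeric vector of nutrient intakes.
#' @param level confidence level, default 0.95.
#' @return A tibble with `x`, `mean`, `lower`, `upper`, `extrapolated`.
#' @export
confidence_band <- function(fit, grid, level = 0.95) {
  stopifnot(inherits(fit, "poly_fit"))
  if (fit$residual_df <= 0) {
    abort("No residual degrees of freedom; band undefined.",
          class = "phasereq_size_error")
  }
  pr <- stats::predict(fit$model, newdata = data.frame(x = grid),
                       se.fit = TRUE)
  half <- qt((1 + level) / 2, fit$residual_df) * pr$se.fit
  tibble::tibble(
    x = grid, mean = unname(pr$fit),
    lower = unname(pr$fit - half), upper = unname(pr$fit + half),
    extrapolated = grid < min(fit$x) | grid > max(fit$x)
  )
}

#' Compare linear and quadratic benchmark fits
#'
#' Fits both degrees and reports their RMSEs and the two-sided p-value
#' of the quadratic coefficient; `improved` is `TRUE` when that
#' p-value falls below `threshold`. Because the models are nested and
#' RMSE is `sqrt(SSE/n)`, `rmse_quadratic <= rmse_linear` always.
#'
#' @param data,nutrient,response as in [fit_polynomial()].
#' @param threshold significance threshold, default 0.05.
#' @return A one-row tibble: `rmse_linear`, `rmse_quadratic`,
#'   `quadratic_term_p`, `improved`.
#' @export
compare_linear_quadratic <- function(data, nutrient,
                                     response = "chicks_per_hen_week",
                                     threshold = 0.05) {
  lin <- fit_polynomial(data, nutrient, response, degree = 1)
  quad <- fit_polynomial(data, nutrient, response, degree = 2)
  p_quad <- unname(quad$term_p_values[3])
  tibble::tibble(
    rmse_linear = lin$rmse,
    rmse_quadratic = quad$rmse,
    quadratic_term_p = p_quad,
    improved = p_quad < threshold
  )
}
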