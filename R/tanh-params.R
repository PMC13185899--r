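# The four-parameter tanh dose-response curve:
#   response(x) = A * tanh(c * x + b) + B
# A: output amplitude (response units), b: dimensionless offset,
# c: gain per nutrient unit, B: output offset (response units).
# Canonical form has A > 0; (A, b, c, B) and (-A, -b, -c, B) describe
# the same curve by oddness of tanh.

#' Construct tanh dose-response parameters
#'
#' @param A output amplitude, response units. Non-zero for a
#'   non-degenerate curve; the canonical representation has `A > 0`.
#' @param b dimensionless input offset.
#' @param c gain per nutrient unit; `c > 0` with `A > 0` gives an
#'   increasing, saturating curve with asymptote `A + B`.
#' @param B output offset, response units.
#' @return An object of class `tanh_params`.
#' @export
#' @examples
#' p <- tanh_params(A = 2, b = -1, c = 0.5, B = 1)
#' predict_response(p, c(0, 2, 10))
tanh_params <- function(A, b, c, B) {
  vals <- c(A = A, b = b, c = c, B = B)
  if (!all(is.finite(vals))) {
    abort("tanh parameters must be finite numbers.",
          class = "phasereq_validation_error")
  }
  structure(as.list(vals), class = "tanh_params")
}

#' @export
format.tanh_params <- function(x, ...) {
  sprintf("tanh_params: A=%.6g b=%.6g c=%.6g B=%.6g", x$A, x$b, x$c, x$B)
}

#' @export
print.tanh_params <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Resolve the sign degeneracy: report the representative with A > 0.
canonicalize_params <- function(p) {
  if (p$A < 0) tanh_params(-p$A, -p$b, -p$c, p$B) else p
}

#' Evaluate the tanh dose-response curve
#'
#' Computes `A * tanh(c * x + b) + B` in original units. The curve is
#' monotone increasing in `x` whenever `A * c > 0` and approaches
#' `A + B` as `x` grows without bound.
#'
#' @param params a [tanh_params()] object or a [fit_tanh_neuron()] fit.
#' @param x numeric vector of nutrient intakes.
#' @return Numeric vector of predicted responses.
#' @export
predict_response <- function(params, x) {
  p <- as_tanh_params(params)
  p$A * tanh(p$c * x + p$b) + p$B
}

as_tanh_params <- function(params) {
  if (inherits(params, "tanh_fit")) return(params$params)
  if (inherits(params, "tanh_params")) return(params)
  if (is.list(params) && all(c("A", "b", "c", "B") %in% names(params))) {
    return(tanh_params(params$A, params$b, params$c, params$B))
  }
  abort("Expected a `tanh_params` object or a tanh fit.",
        class = "phasereq_validation_error")
}
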