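# Requirement derivation from a fitted tanh curve. The asymptotic
# response is A + B (the ceiling under unlimited intake); the intake
# achieving fraction p of it solves A*tanh(c*x + b) + B = p*(A + B),
# giving the closed form
#   Req_p = (atanh((p*(A + B) - B) / A) - b) / c,
# which at p = 0.95 reduces to (atanh(0.95 - 0.05*B/A) - b) / c.

#' Asymptotic response of a tanh dose-response curve
#'
#' The model-predicted ceiling as nutrient intake grows without bound:
#' `A + B` for a canonical (`A > 0`) parameterization.
#'
#' @param params a [tanh_params()] object or a tanh fit.
#' @return Asymptotic response, response units.
#' @export
#' @examples
#' asymptotic_response(tanh_params(2, -1, 0.5, 1))  # 3
asymptotic_response <- function(params) {
  p <- canonicalize_params(as_tanh_params(params))
  p$A + p$B
}

#' Nutrient requirement at a fraction of the asymptotic response
#'
#' Computes `Req_p`, the intake at which the fitted curve reaches
#' `p` (default 0.95) of its asymptote, in closed form. The estimate is
#' valid only for an increasing curve (`c > 0` after canonicalization)
#' whose response range actually contains the target, i.e.
#' `|(p*(A+B) - B)/A| < 1`; otherwise `valid` is `FALSE` with a reason
#' and `req` is `NA`.
#'
#' @param params a [tanh_params()] object or a `tanh_fit`.
#' @param p response fraction in (0, 1), default 0.95.
#' @return A one-row tibble: `p`, `req`, `asymptote`, `target_response`,
#'   `valid`, `invalid_reason`.
#' @export
#' @examples
#' requirement_at_fraction(tanh_params(1, 0, 1, 0))$req  # atanh(0.95)
requirement_at_fraction <- function(params, p = 0.95) {
  if (!is.numeric(p) || length(p) != 1 || !(p > 0 && p < 1)) {
    abort("`p` must be a single number in (0, 1).",
          class = "phasereq_validation_error")
  }
  pars <- canonicalize_params(as_tanh_params(params))
  asym <- pars$A + pars$B
  target <- p * asym
  theta <- (target - pars$B) / pars$A
  valid <- TRUE
  reason <- ""
  req <- NA_real_
  if (pars$c <= 0) {
    valid <- FALSE
    reason <- "non-increasing curve"
  } else if (abs(theta) >= 1) {
    valid <- FALSE
    reason <- "target outside response range"
  } else {
    req <- (atanh(theta) - pars$b) / pars$c
  }
  tibble::tibble(p = p, req = req, asymptote = asym,
                 target_response = target, valid = valid,
                 invalid_reason = reason)
}

#' Numeric requirement oracle (bracketing bisection)
#'
#' Solves `A*tanh(c*x + b) + B = p*(A + B)` by bisection to absolute
#' tolerance 1e-10, independently of the closed form. A verification
#' utility: the closed form and this root agree to 1e-8 on any valid
#' parameter set.
#'
#' @param params a [tanh_params()] object.
#' @param p response fraction in (0, 1).
#' @return The root, nutrient units.
#' @export
requirement_oracle <- function(params, p = 0.95) {
  pars <- canonicalize_params(as_tanh_params(params))
  if (pars$c <= 0) {
    abort("Oracle undefined: non-increasing curve.",
          class = "phasereq_oracle_error")
  }
  target <- p * (pars$A + pars$B)
  g <- function(x) predict_response(pars, x) - target
  # expand a bracket around the curve midpoint -b/c
  center <- -pars$b / pars$c
  half <- 1 / abs(pars$c)
  for (i in 1:200) {
    lo <- center - half
    hi <- center + half
    if (g(lo) < 0 && g(hi) > 0) {
      while (hi - lo > 1e-10) {
        mid <- (lo + hi) / 2
        if (g(mid) < 0) lo <- mid else hi <- mid
      }
      return((lo + hi) / 2)
    }
    half <- half * 2
  }
  abort("Oracle could not bracket the target response.",
        class = "phasereq_oracle_error")
}
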