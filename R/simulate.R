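# Synthetic flock-week data with the statistical structure the analysis
# assumes: a saturating tanh mean response in nutrient intake plus
# additive homoscedastic Gaussian noise, phase-specific sample sizes and
# noise levels.

#' Solve tanh parameters that hit a prescribed requirement
#'
#' Inverts the closed-form requirement: given the intake `req` at which
#' the curve reaches fraction `p` (default 0.95) of its asymptote, the
#' asymptotic response `S`, the lower plateau `L` (response as intake
#' falls away) and the curve midpoint `x_mid` (intake where the response
#' is halfway, `tanh` argument zero), returns the unique increasing
#' curve through those landmarks:
#' `A = (S - L)/2`, `B = (S + L)/2`,
#' `c = atanh((p*S - B)/A) / (req - x_mid)`, `b = -c * x_mid`.
#'
#' @param req target requirement, nutrient units.
#' @param asymptote `S`, response units; must exceed `lower`.
#' @param lower `L`, lower plateau, response units.
#' @param x_mid curve midpoint, nutrient units; must be below `req`.
#' @param p response fraction in (0, 1), default 0.95.
#' @return A [tanh_params()] object with `A > 0` and `c > 0`.
#' @export
#' @examples
#' p <- solve_params_for_requirement(453.4, asymptote = 4.2, lower = 0,
#'                                   x_mid = 438.4)
#' requirement_at_fraction(p)$req
solve_params_for_requirement <- function(req, asymptote, lower = 0,
                                         x_mid, p = 0.95) {
  if (!(lower < asymptote)) {
    abort("`lower` must be strictly below `asymptote`.",
          class = "phasereq_validation_error")
  }
  if (!(x_mid < req)) {
    abort("`x_mid` must lie below `req` for an increasing curve.",
          class = "phasereq_validation_error")
  }
  if (!(p > 0 && p < 1)) {
    abort("`p` must lie in (0, 1).", class = "phasereq_validation_error")
  }
  A <- (asymptote - lower) / 2
  B <- (asymptote + lower) / 2
  theta <- (p * asymptote - B) / A
  if (!(abs(theta) < 1)) {
    abort("Target fraction is unreachable: (p*S - B)/A must lie in (-1, 1).",
          class = "phasereq_validation_error")
  }
  cc <- atanh(theta) / (req - x_mid)
  tanh_params(A = A, b = -cc * x_mid, c = cc, B = B)
}

#' Simulate one phase's flock-week records
#'
#' Draws nutrient intakes uniformly on `intake_range`, computes the mean
#' response on the tanh curve `params`, adds independent Gaussian noise
#' with standard deviation `noise_sd`, and draws hen ages uniformly from
#' the phase's age interval. Deterministic given `seed`.
#'
#' @param n number of flock-week records (>= 4).
#' @param phase `"early"`, `"mid"` or `"late"`.
#' @param params true curve, a [tanh_params()] object.
#' @param intake_range length-2 numeric, uniform intake support.
#' @param noise_sd response-noise standard deviation (>= 0),
#'   chicks/hen/week.
#' @param nutrient intake column to fill: one of `"me_intake"`,
#'   `"dlys_intake"`, `"dmet_intake"`, `"dthr_intake"`.
#' @param seed integer seed.
#' @return A tibble in the intakes-mode record layout (unused intake
#'   columns are `NA`), with a `phase` column.
#' @export
simulate_phase <- function(n, phase, params, intake_range, noise_sd,
                           nutrient = "me_intake", seed = 1L) {
  if (n < 4) abort("`n` must be at least 4.", class = "phasereq_validation_error")
  if (length(intake_range) != 2 || !(intake_range[1] < intake_range[2])) {
    abort("`intake_range` must be (lo, hi) with lo < hi.",
          class = "phasereq_validation_error")
  }
  if (noise_sd < 0) {
    abort("`noise_sd` must be non-negative.",
          class = "phasereq_validation_error")
  }
  phase <- match.arg(phase, phase_levels())
  nutrient <- match.arg(nutrient, intake_cols)
  params <- as_tanh_params(params)
  pt <- phase_table()
  ages <- pt[pt$phase == phase, ]
  with_seed(seed, {
    x <- runif(n, intake_range[1], intake_range[2])
    eps <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
    age <- sample(seq(ages$age_min, ages$age_max), n, replace = TRUE)
    out <- tibble::tibble(
      flock_id = sprintf("sim-%s-%04d", phase, seq_len(n)),
      age_weeks = as.integer(age),
      me_intake = NA_real_, dlys_intake = NA_real_,
      dmet_intake = NA_real_, dthr_intake = NA_real_,
      chicks_per_hen_week = predict_response(params, x) + eps,
      phase = factor(phase, levels = phase_levels())
    )
    out[[nutrient]] <- x
    out
  })
}

# Assumed scenario geometry (not printed in the source study): response
# asymptotes and lower plateaus per phase, curve midpoint offset and
# intake-range offsets per nutrient, all in original units. Plateaus sit
# several noise SDs above zero so the additive-Gaussian response model
# essentially never produces negative chick counts.
scenario_geometry <- function() {
  list(
    asymptote = c(early = 4.2, mid = 5.6, late = 4.4),
    lower = c(early = 1.5, mid = 2.0, late = 1.5),
    # x_mid = req - mid_offset; range = [req - lo_offset, req + hi_offset]
    offsets = list(
      me = c(mid = 15, lo = 45, hi = 20),
      dlys = c(mid = 0.10, lo = 0.28, hi = 0.06),
      dmet = c(mid = 0.10, lo = 0.28, hi = 0.06),
      dthr = c(mid = 0.10, lo = 0.28, hi = 0.06)
    )
  )
}

#' Study-design scenario presets
#'
#' The twelve nutrient-by-phase scenarios used for validation: true
#' requirement targets set to the study's reported point estimates
#' (ME 453.4/448.9/448.3 kcal/d; dLys 0.95/1.03/0.89, dMet
#' 0.65/0.68/0.59, dThr 0.77/0.80/0.69 g/d for early/mid/late), phase
#' sample sizes 515/1471/699, and response-noise standard deviations
#' equal to the reported model RMSEs (ME 0.41/0.12/0.20; dLys and dMet
#' 0.41/0.20/0.21; dThr 0.408/0.212/0.206 chicks/hen/week). Curve
#' asymptotes, the lower plateau, midpoints and intake ranges are
#' assumed defaults documented in the methods vignette, not reported
#' values.
#'
#' @return A tibble with one row per scenario: `nutrient`, `phase`,
#'   `n`, `x_lo`, `x_hi`, `noise_sd`, `true_req`, and the true curve
#'   parameters `A`, `b`, `c`, `B`.
#' @export
#' @examples
#' scenario_presets()
scenario_presets <- function() {
  req <- tibble::tribble(
    ~nutrient, ~phase, ~true_req, ~noise_sd,
    "me",   "early", 453.4, 0.41,
    "me",   "mid",   448.9, 0.12,
    "me",   "late",  448.3, 0.20,
    "dlys", "early", 0.95,  0.41,
    "dlys", "mid",   1.03,  0.20,
    "dlys", "late",  0.89,  0.21,
    "dmet", "early", 0.65,  0.41,
    "dmet", "mid",   0.68,  0.20,
    "dmet", "late",  0.59,  0.21,
    "dthr", "early", 0.77,  0.408,
    "dthr", "mid",   0.80,  0.212,
    "dthr", "late",  0.69,  0.206
  )
  sizes <- c(early = 515L, mid = 1471L, late = 699L)
  geom <- scenario_geometry()
  req$n <- sizes[req$phase]
  rows <- purrr::pmap(req, function(nutrient, phase, true_req, noise_sd, n) {
    off <- geom$offsets[[nutrient]]
    pars <- solve_params_for_requirement(
      req = true_req,
      asymptote = geom$asymptote[[phase]],
      lower = geom$lower[[phase]],
      x_mid = true_req - off[["mid"]]
    )
    tibble::tibble(
      nutrient = nutrient, phase = phase, n = n,
      x_lo = true_req - off[["lo"]], x_hi = true_req + off[["hi"]],
      noise_sd = noise_sd, true_req = true_req,
      A = pars$A, b = pars$b, c = pars$c, B = pars$B
    )
  })
  out <- dplyr::bind_rows(rows)
  out$phase <- factor(out$phase, levels = phase_levels())
  out
}

#' Simulate a full multi-scenario dataset
#'
#' Generates one dataset per preset row and stacks them. Each scenario
#' gets an independent sub-seed derived from `seed`, so the result is
#' deterministic given `seed` and any subset of scenarios reproduces
#' exactly.
#'
#' @param presets tibble as returned by [scenario_presets()]; may be a
#'   subset of rows.
#' @param seed master integer seed.
#' @return A tibble of simulated flock-week records with `nutrient` and
#'   `phase` columns identifying the scenario.
#' @export
simulate_scenarios <- function(presets = scenario_presets(), seed = 1L) {
  seeds <- derive_seeds(seed, nrow(presets))
  out <- purrr::map2(seq_len(nrow(presets)), seeds, function(i, s) {
    pr <- presets[i, ]
    rec <- simulate_phase(
      n = pr$n, phase = as.character(pr$phase),
      params = tanh_params(pr$A, pr$b, pr$c, pr$B),
      intake_range = c(pr$x_lo, pr$x_hi),
      noise_sd = pr$noise_sd,
      nutrient = paste0(pr$nutrient, "_intake"),
      seed = s
    )
    rec$nutrient <- pr$nutrient
    rec
  })
  dplyr::bind_rows(out)
}
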