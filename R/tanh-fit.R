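# Single-neuron tanh dose-response fitting with Bayesian regularization.
#
# Both axes are min-max scaled to [-1, 1]; in scaled space the objective
#   F = beta * E_D + alpha * E_W,
#   E_D = 1/2 * sum(residual^2),  E_W = 1/2 * (A^2 + b^2 + c^2 + B^2),
# is minimized by damped least squares (Levenberg-Marquardt, via
# minpack.lm on the sqrt-weighted augmented residual vector). After each
# inner solve the hyperparameters are re-estimated by the evidence
# approximation with a Gauss-Newton Hessian:
#   gamma = 4 - alpha * tr(H^-1),  H = beta * J'J + alpha * I,
#   alpha = gamma / (2 E_W),       beta = (n - gamma) / (2 E_D),
# iterating to joint convergence. The best of `n_restarts` seeded random
# starts (by final objective, ties by RMSE) is kept and its parameters
# are back-transformed analytically to original units, canonicalized to
# A > 0.

#' Control settings for the tanh neuron fitter
#'
#' @param n_restarts number of random multi-starts (default 10); initial
#'   scaled parameters are drawn uniformly from `[-1, 1]`.
#' @param max_iter maximum outer (hyperparameter) iterations per start.
#' @param tol relative objective-change tolerance for outer convergence;
#'   hyperparameters must additionally be stable to relative 1e-6.
#' @param seed integer seed for the restart draws.
#' @param init optional [tanh_params()] warm start in original units,
#'   used as the first start (bootstrap refits use the full-data fit
#'   here); the remaining `n_restarts - 1` starts are random.
#' @param inner_maxiter Levenberg-Marquardt iteration cap per inner solve.
#' @return A list of class `tanh_control`.
#' @export
tanh_control <- function(n_restarts = 10L, max_iter = 300L, tol = 1e-9,
                         seed = 1L, init = NULL, inner_maxiter = 100L) {
  if (n_restarts < 1) abort("`n_restarts` must be >= 1.",
                            class = "phasereq_validation_error")
  structure(list(n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), init = init,
                 inner_maxiter = as.integer(inner_maxiter)),
            class = "tanh_control")
}

# One full regularized fit from a single scaled start. Returns NULL on
# numerical failure (treated as a diverged restart).
fit_one_start <- function(xs, ys, w0, control) {
  n <- length(xs)
  # small positive initial weight penalty keeps the Gauss-Newton Hessian
  # invertible even in flat (unidentified) directions; the evidence
  # updates take over from the first outer iteration
  alpha <- 0.01
  beta <- 1
  w <- w0
  trace <- numeric(0)
  f_old <- Inf
  converged <- FALSE

  model_parts <- function(w) {
    th <- tanh(w[3] * xs + w[2])
    list(th = th, r = ys - (w[1] * th + w[4]))
  }
  data_jac <- function(w, th) {
    s <- 1 - th^2
    cbind(th, w[1] * s, w[1] * s * xs, rep(1, n))
  }

  for (iter in seq_len(control$max_iter)) {
    sa <- sqrt(alpha)
    sb <- sqrt(beta)
    res_fn <- function(w) {
      mp <- model_parts(w)
      c(sb * mp$r, sa * w)
    }
    jac_fn <- function(w) {
      mp <- model_parts(w)
      rbind(-sb * data_jac(w, mp$th), diag(sa, 4))
    }
    sol <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = w, fn = res_fn, jac = jac_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = control$inner_maxiter, ftol = 1e-13, ptol = 1e-13
        )
      )),
      error = function(e) NULL
    )
    if (is.null(sol)) return(NULL)
    w <- unname(sol$par)
    mp <- model_parts(w)
    e_d <- 0.5 * sum(mp$r^2)
    e_w <- 0.5 * sum(w^2)
    jj <- crossprod(data_jac(w, mp$th))
    h <- beta * jj + diag(alpha, 4)
    tr_hinv <- tryCatch(sum(diag(solve(h))), error = function(e) NA_real_)
    if (!is.finite(tr_hinv)) return(NULL)
    gamma <- min(max(4 - alpha * tr_hinv, 0), 4)
    f_new <- beta * e_d + alpha * e_w
    trace <- c(trace, f_new)
    alpha_new <- gamma / max(2 * e_w, 1e-12)
    beta_new <- min((n - gamma) / max(2 * e_d, 1e-12), 1e12)
    obj_ok <- abs(f_new - f_old) <= control$tol * max(abs(f_new), 1e-12)
    hyp_ok <- abs(alpha_new - alpha) <= 1e-6 * max(abs(alpha), 1e-8) &&
      abs(beta_new - beta) <= 1e-6 * max(abs(beta), 1e-8)
    alpha <- alpha_new
    beta <- beta_new
    f_old <- f_new
    if (obj_ok && hyp_ok) {
      converged <- TRUE
      break
    }
  }
  mp <- model_parts(w)
  list(w = w, alpha = alpha, beta = beta, gamma = gamma,
       e_d = 0.5 * sum(mp$r^2), e_w = 0.5 * sum(w^2),
       objective = f_old, trace = trace, converged = converged,
       rmse_scaled = sqrt(mean(mp$r^2)))
}

# Analytic back-transformation of scaled-space parameters to original
# units: with xs = ax*x + bx and ys = ay*y + by,
#   y = (As*tanh((cs*ax) x + (cs*bx + bs)) + Bs - by) / ay.
backtransform_params <- function(w, sx, sy) {
  tanh_params(
    A = w[1] / sy$slope,
    b = w[3] * sx$intercept + w[2],
    c = w[3] * sx$slope,
    B = (w[4] - sy$intercept) / sy$slope
  )
}

#' Fit the single-neuron tanh dose-response model
#'
#' Fits `response = A * tanh(c * nutrient + b) + B` by regularized
#' least squares with evidence-framework hyperparameter updates (see
#' the package vignette for the algorithm). Deterministic given
#' `control$seed`.
#'
#' @param data data frame of flock-week records (complete cases of the
#'   two chosen columns are used; at least 5 required).
#' @param nutrient name of the nutrient-intake column (x-axis).
#' @param response name of the response column, default
#'   `"chicks_per_hen_week"`.
#' @param control a [tanh_control()].
#' @return An object of class `tanh_fit` with elements `params`
#'   ([tanh_params()] in original units, `A > 0`), `scaler_x`,
#'   `scaler_y`, `rmse` (sqrt(SSE/n), response units), `alpha`, `beta`,
#'   `gamma` (effective number of parameters), `objective_trace`,
#'   `n_restarts_used`, `converged`, `seed`, `n`, and the data columns
#'   used.
#' @export
#' @examples
#' pr <- scenario_presets()[2, ]  # ME, mid phase
#' d <- simulate_phase(200, "mid", tanh_params(pr$A, pr$b, pr$c, pr$B),
#'                     c(pr$x_lo, pr$x_hi), noise_sd = 0.1, seed = 7)
#' fit <- fit_tanh_neuron(d, "me_intake")
#' tidy(fit)
fit_tanh_neuron <- function(data, nutrient,
                            response = "chicks_per_hen_week",
                            control = tanh_control()) {
  stopifnot(inherits(control, "tanh_control"))
  for (col in c(nutrient, response)) {
    if (!col %in% names(data)) {
      abort(paste0("Column not found: ", col),
            class = "phasereq_schema_error")
    }
  }
  ok <- stats::complete.cases(data[[nutrient]], data[[response]])
  x <- data[[nutrient]][ok]
  y <- data[[response]][ok]
  n <- length(x)
  if (n < 5) {
    abort("At least 5 complete (nutrient, response) cases are required.",
          class = "phasereq_size_error")
  }
  if (diff(range(x)) == 0) {
    abort("Nutrient intake is constant; the dose-response design is degenerate.",
          class = "phasereq_degenerate_error")
  }
  sx <- new_scaler(range(x))
  sy <- new_scaler(range(y))
  xs <- scaler_apply(sx, x)
  ys <- scaler_apply(sy, y)

  starts <- with_seed(control$seed, {
    replicate(control$n_restarts, runif(4, -1, 1), simplify = FALSE)
  })
  if (!is.null(control$init)) {
    p0 <- as_tanh_params(control$init)
    # invert the back-transformation to seed the first start
    cs <- p0$c / sx$slope
    starts[[1]] <- c(p0$A * sy$slope, p0$b - cs * sx$intercept, cs,
                     p0$B * sy$slope + sy$intercept)
  }
  fits <- lapply(starts, function(w0) fit_one_start(xs, ys, w0, control))
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    abort("All restarts diverged; cannot fit the tanh neuron.",
          class = "phasereq_convergence_error")
  }
  obj <- vapply(fits, function(f) f$objective, numeric(1))
  rms <- vapply(fits, function(f) f$rmse_scaled, numeric(1))
  best <- fits[[order(obj, rms)[1]]]

  params <- canonicalize_params(backtransform_params(best$w, sx, sy))
  resid <- y - predict_response(params, x)
  structure(
    list(params = params, scaler_x = sx, scaler_y = sy,
         rmse = sqrt(mean(resid^2)),
         alpha = best$alpha, beta = best$beta, gamma = best$gamma,
         objective_trace = best$trace,
         n_restarts_used = length(fits), converged = best$converged,
         seed = control$seed, n = n,
         nutrient = nutrient, response = response, x = x, y = y),
    class = "tanh_fit"
  )
}

#' @export
print.tanh_fit <- function(x, ...) {
  cat("Single-neuron tanh dose-response fit\n")
  cat("  ", format(x$params), "\n", sep = "")
  cat(sprintf("  n = %d, RMSE = %.4g, gamma = %.3g, converged: %s\n",
              x$n, x$rmse, x$gamma, x$converged))
  invisible(x)
}

#' Predict from a tanh fit
#'
#' @param object a `tanh_fit`.
#' @param newdata numeric vector of nutrient intakes, or a data frame
#'   containing the fitted nutrient column; defaults to the training
#'   intakes.
#' @param ... unused.
#' @return Numeric vector of predicted responses in original units.
#' @export
predict.tanh_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) {
    object$x
  } else if (is.data.frame(newdata)) {
    newdata[[object$nutrient]]
  } else {
    newdata
  }
  predict_response(object$params, x)
}

#' @export
tidy.tanh_fit <- function(x, ...) {
  tibble::tibble(
    term = c("A", "b", "c", "B"),
    estimate = c(x$params$A, x$params$b, x$params$c, x$params$B)
  )
}

#' @export
glance.tanh_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, rmse = x$rmse, alpha = x$alpha, beta = x$beta,
    gamma = x$gamma, asymptote = x$params$A + x$params$B,
    converged = x$converged, n_restarts_used = x$n_restarts_used,
    seed = x$seed
  )
}

#' Root-mean-square error of a fit on data
#'
#' Uses the package-wide convention `sqrt(SSE / n)` so tanh and
#' polynomial fits are directly comparable.
#'
#' @param fit a `tanh_fit` (or any object with a `predict` method over
#'   numeric x).
#' @param x,y numeric vectors.
#' @return RMSE in response units.
#' @export
fit_rmse <- function(fit, x, y) {
  sqrt(mean((y - predict(fit, x))^2))
}

#' Bootstrap confidence band for the fitted mean response
#'
#' Case-resampling bootstrap: each replicate resamples records with
#' replacement, refits the tanh neuron (warm-started at the full-data
#' fit), and predicts on `grid`; the band is the pointwise percentile
#' envelope of the replicate mean curves. Deterministic given `seed`.
#'
#' @param data,nutrient,response as in [fit_tanh_neuron()].
#' @param grid numeric vector of nutrient intakes to evaluate.
#' @param n_boot number of replicates (default 100).
#' @param level envelope level (default 0.95).
#' @param seed integer seed.
#' @param control a [tanh_control()] for the full-data fit.
#' @return A tibble with columns `x`, `mean` (full-data fit), `lower`,
#'   `upper`, plus attributes `n_failed` and `fit`.
#' @export
curve_band <- function(data, nutrient, response = "chicks_per_hen_week",
                       grid, n_boot = 100, level = 0.95, seed = 1L,
                       control = tanh_control(seed = seed)) {
  fit <- fit_tanh_neuron(data, nutrient, response, control)
  boot <- bootstrap_tanh(data, nutrient, response, fit, n_boot, seed,
                         p = NULL)
  if (boot$n_failed > 0.2 * n_boot) {
    abort(sprintf("Bootstrap band failed: %d of %d replicates diverged.",
                  boot$n_failed, n_boot),
          class = "phasereq_inference_error")
  }
  preds <- vapply(boot$fits, function(f) predict_response(f$params, grid),
                  numeric(length(grid)))
  preds <- matrix(preds, nrow = length(grid))
  lo <- apply(preds, 1, quantile, probs = (1 - level) / 2, type = 7)
  hi <- apply(preds, 1, quantile, probs = (1 + level) / 2, type = 7)
  out <- tibble::tibble(x = grid, mean = predict_response(fit$params, grid),
                        lower = lo, upper = hi)
  attr(out, "n_failed") <- boot$n_failed
  attr(out, "fit") <- fit
  out
}

# Shared bootstrap engine: resample-refit with derived sub-seeds and a
# warm start at the full-data estimate plus one random restart.
bootstrap_tanh <- function(data, nutrient, response, fit, n_boot, seed,
                           p = 0.95, boot_restarts = 2L) {
  ok <- stats::complete.cases(data[[nutrient]], data[[response]])
  d <- tibble::tibble(x = data[[nutrient]][ok], y = data[[response]][ok])
  n <- nrow(d)
  seeds <- derive_seeds(seed, n_boot)
  fits <- vector("list", n_boot)
  failed_seeds <- integer(0)
  for (r in seq_len(n_boot)) {
    idx <- with_seed(seeds[r], sample.int(n, n, replace = TRUE))
    ctl <- tanh_control(n_restarts = boot_restarts, seed = seeds[r],
                        init = fit$params)
    rep_fit <- tryCatch(
      fit_tanh_neuron(d[idx, ], "x", "y", ctl),
      error = function(e) NULL
    )
    if (is.null(rep_fit) || !rep_fit$converged) {
      failed_seeds <- c(failed_seeds, seeds[r])
    } else {
      fits[[r]] <- rep_fit
    }
  }
  list(fits = Filter(Negate(is.null), fits),
       n_failed = length(failed_seeds), failed_seeds = failed_seeds)
}
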