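test_that("noiseless curves are recovered to numerical precision", {
  truth <- tanh_params(1, -3, 0.01, 1)
  d <- withr::with_seed(2, tibble::tibble(x = runif(200, 50, 550)))
  d$y <- predict_response(truth, d$x)
  fit <- fit_tanh_neuron(d, "x", "y")
  expect_lt(fit_rmse(fit, d$x, d$y), 1e-6)
  expect_true(fit$converged)
  # predictions match truth well beyond the fitted range too
  grid <- seq(0, 700, by = 25)
  expect_lt(max(abs(predict(fit, grid) - predict_response(truth, grid))),
            1e-4)
})

test_that("the sign degeneracy is resolved to a canonical A > 0", {
  truth <- tanh_params(-1.4, 36, -0.08, 2.6)  # mirror of an increasing curve
  d <- withr::with_seed(3, tibble::tibble(x = runif(120, 410, 470)))
  d$y <- predict_response(truth, d$x)
  fit <- fit_tanh_neuron(d, "x", "y")
  expect_gt(fit$params$A, 0)
  expect_gt(fit$params$c, 0)
  expect_lt(fit_rmse(fit, d$x, d$y), 1e-6)
})

test_that("fitting is deterministic given the seed", {
  d <- simulate_preset("me", "late", seed = 21, n = 120)
  f1 <- fit_tanh_neuron(d, "me_intake", control = tanh_control(seed = 4))
  f2 <- fit_tanh_neuron(d, "me_intake", control = tanh_control(seed = 4))
  expect_identical(tidy(f1), tidy(f2))
})

test_that("fit is invariant to record order and equivariant to units", {
  d <- simulate_preset("me", "mid", seed = 33, n = 300)
  f1 <- fit_tanh_neuron(d, "me_intake", control = tanh_control(seed = 1))
  d2 <- d[withr::with_seed(9, sample(nrow(d))), ]
  f2 <- fit_tanh_neuron(d2, "me_intake", control = tanh_control(seed = 1))
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-6)

  # kcal -> Mcal: requirement scales by 1/1000, c by 1000
  d3 <- dplyr::mutate(d, me_intake = me_intake / 1000)
  f3 <- fit_tanh_neuron(d3, "me_intake", control = tanh_control(seed = 1))
  r1 <- requirement_at_fraction(f1$params)$req
  r3 <- requirement_at_fraction(f3$params)$req
  expect_equal(r3 * 1000, r1, tolerance = 1e-4)
})

test_that("degenerate inputs raise typed errors; constant response shrinks A", {
  d <- tibble::tibble(x = rep(450, 20), y = rnorm(20))
  expect_error(fit_tanh_neuron(d, "x", "y"),
               class = "phasereq_degenerate_error")
  expect_error(fit_tanh_neuron(tibble::tibble(x = 1:4, y = 1:4), "x", "y"),
               class = "phasereq_size_error")

  flat <- tibble::tibble(x = seq(400, 470, length.out = 60), y = rep(3.1, 60))
  fit <- fit_tanh_neuron(flat, "x", "y")
  # no signal: regularization keeps the curve essentially flat and the
  # requirement is flagged invalid downstream or sits outside the data
  est <- requirement_at_fraction(fit$params)
  amp_small <- abs(fit$params$A) < 0.05
  expect_true(amp_small || !est$valid || est$req > max(flat$x))
})

test_that("predictions follow the closed-form curve", {
  p <- tanh_params(2, -1, 0.5, 1)
  fit <- structure(list(params = p, nutrient = "x", x = c(0, 2)),
                   class = "tanh_fit")
  expect_equal(predict(fit, 2), 1 + 2 * tanh(0))        # midpoint: B
  expect_equal(predict(fit, 1e6), 3, tolerance = 1e-9)  # asymptote A + B
  xs <- c(0, 1, 4)
  expect_equal(predict(fit, xs), 2 * tanh(0.5 * xs - 1) + 1)
})

test_that("RMSE follows the sqrt(SSE/n) convention and tracks noise", {
  d <- simulate_preset("me", "mid", seed = 17, n = 1471, noise_sd = 0.12)
  fit <- fit_tanh_neuron(d, "me_intake", control = tanh_control(seed = 17))
  manual <- sqrt(mean((d$chicks_per_hen_week -
                         predict(fit, d$me_intake))^2))
  expect_equal(fit_rmse(fit, d$me_intake, d$chicks_per_hen_week), manual,
               tolerance = 1e-12)
  expect_equal(fit$rmse, manual, tolerance = 1e-12)
  expect_lt(abs(fit$rmse - 0.12) / 0.12, 0.10)

  noiseless <- simulate_preset("me", "mid", seed = 18, n = 200, noise_sd = 0)
  f0 <- fit_tanh_neuron(noiseless, "me_intake")
  expect_lt(f0$rmse, 1e-8)
})

test_that("regularization vanishes as noise goes to zero (gamma -> 4)", {
  d <- simulate_preset("dlys", "mid", seed = 6, n = 400, noise_sd = 0)
  fit <- fit_tanh_neuron(d, "dlys_intake")
  expect_equal(fit$gamma, 4, tolerance = 1e-3)
  expect_lt(fit$alpha / fit$beta, 1e-8)
})

test_that("scaled-space and original-unit parameterizations agree", {
  d <- simulate_preset("dthr", "late", seed = 40, n = 250)
  fit <- fit_tanh_neuron(d, "dthr_intake", control = tanh_control(seed = 2))
  # evaluate through the scalers: map x to [-1,1], apply the scaled-space
  # parameters recovered by inverting the back-transformation, map back
  sx <- fit$scaler_x
  sy <- fit$scaler_y
  p <- fit$params
  cs <- p$c / sx$slope
  ws <- c(p$A * sy$slope, p$b - cs * sx$intercept, cs,
          p$B * sy$slope + sy$intercept)
  x <- d$dthr_intake
  xs <- sx$slope * x + sx$intercept
  ys <- ws[1] * tanh(ws[3] * xs + ws[2]) + ws[4]
  via_scaler <- (ys - sy$intercept) / sy$slope
  expect_equal(via_scaler, predict(fit, x), tolerance = 1e-9)
})

test_that("bootstrap curve band behaves on noiseless and noisy data", {
  d0 <- simulate_preset("me", "late", seed = 55, n = 100, noise_sd = 0)
  grid <- seq(min(d0$me_intake), max(d0$me_intake), length.out = 9)
  b0 <- curve_band(d0, "me_intake", grid = grid, n_boot = 20, seed = 5)
  expect_lt(max(b0$upper - b0$lower), 1e-6)

  d <- simulate_preset("me", "late", seed = 56, n = 250)
  b1 <- curve_band(d, "me_intake", grid = grid, n_boot = 30, seed = 5)
  b2 <- curve_band(d, "me_intake", grid = grid, n_boot = 30, seed = 5)
  expect_identical(b1$lower, b2$lower)
  expect_true(all(b1$lower <= b1$mean & b1$mean <= b1$upper))
  expect_lte(attr(b1, "n_failed"), 0.2 * 30)
})
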