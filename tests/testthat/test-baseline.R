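# Independent oracle: normal-equations OLS with hat-matrix standard
# errors, kept free of lm().
ols_oracle <- function(x, y, degree) {
  X <- cbind(1, x)
  if (degree == 2) X <- cbind(X, x^2)
  XtX_inv <- solve(crossprod(X))
  beta <- XtX_inv %*% crossprod(X, y)
  resid <- y - X %*% beta
  sse <- sum(resid^2)
  df <- length(y) - ncol(X)
  sigma2 <- sse / df
  se <- sqrt(diag(XtX_inv) * sigma2)
  tval <- beta / se
  list(beta = unname(drop(beta)), sse = sse, df = df, sigma2 = sigma2,
       p = unname(2 * pt(-abs(drop(tval)), df)),
       se_mean = function(x0) {
         X0 <- cbind(1, x0)
         if (degree == 2) X0 <- cbind(X0, x0^2)
         sqrt(rowSums((X0 %*% XtX_inv) * X0) * sigma2)
       })
}

test_that("exact line and parabola are recovered with zero RMSE", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1)
  f <- fit_polynomial(d, "x", "y", degree = 1)
  expect_equal(unname(f$coefficients), c(1, 2), tolerance = 1e-10)
  expect_equal(f$r, 1)
  expect_equal(f$rmse, 0, tolerance = 1e-10)
  expect_equal(f$residual_df, 8)

  d2 <- tibble::tibble(x = -2:2, y = (-2:2)^2)
  f2 <- fit_polynomial(d2, "x", "y", degree = 2)
  expect_equal(unname(f2$coefficients), c(0, 0, 1), tolerance = 1e-10)
  expect_equal(f2$rmse, 0, tolerance = 1e-10)
})

test_that("coefficients and p-values match a normal-equations oracle", {
  for (degree in 1:2) {
    d <- withr::with_seed(31, {
      x <- runif(50, 0, 10)
      tibble::tibble(x = x, y = 1.5 - 0.4 * x + 0.07 * x^2 + rnorm(50, 0, 0.3))
    })
    f <- fit_polynomial(d, "x", "y", degree = degree)
    o <- ols_oracle(d$x, d$y, degree)
    expect_equal(unname(f$coefficients), o$beta, tolerance = 1e-10)
    expect_equal(unname(f$term_p_values), o$p, tolerance = 1e-10)
    expect_equal(f$rmse, sqrt(o$sse / 50), tolerance = 1e-12)
  }
})

test_that("r matches Pearson correlation and r^2 the R-squared identity", {
  d <- withr::with_seed(8, tibble::tibble(x = rnorm(40), y = rnorm(40)))
  f <- fit_polynomial(d, "x", "y", degree = 1)
  expect_equal(f$r, cor(d$x, d$y), tolerance = 1e-14)
  r2 <- 1 - sum((d$y - predict(f))^2) / sum((d$y - mean(d$y))^2)
  expect_equal(f$r^2, r2, tolerance = 1e-12)
})

test_that("fits are invariant to record order", {
  d <- withr::with_seed(5, tibble::tibble(x = runif(30), y = runif(30)))
  f1 <- fit_polynomial(d, "x", "y", degree = 2)
  f2 <- fit_polynomial(d[sample(30), ], "x", "y", degree = 2)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)
})

test_that("degenerate designs raise typed errors", {
  d <- tibble::tibble(x = rep(1, 10), y = rnorm(10))
  expect_error(fit_polynomial(d, "x", "y"), class = "phasereq_degenerate_error")
  expect_error(fit_polynomial(tibble::tibble(x = 1:2, y = 1:2), "x", "y"),
               class = "phasereq_size_error")
})

test_that("confidence band matches the hat-matrix oracle and its geometry", {
  d <- withr::with_seed(77, tibble::tibble(x = runif(10, 0, 4)))
  d$y <- 2 + 0.5 * d$x + withr::with_seed(78, rnorm(10, 0, 0.2))
  f <- fit_polynomial(d, "x", "y", degree = 1)
  grid <- seq(0, 5, by = 0.5)
  band <- confidence_band(f, grid, level = 0.95)
  o <- ols_oracle(d$x, d$y, 1)
  half <- qt(0.975, o$df) * o$se_mean(grid)
  expect_equal(band$upper - band$mean, half, tolerance = 1e-10)
  expect_equal(band$mean - band$lower, half, tolerance = 1e-10)
  expect_identical(band$extrapolated, grid < min(d$x) | grid > max(d$x))

  # narrowest at the design mean for a straight-line fit
  gm <- c(mean(d$x), grid)
  bm <- confidence_band(f, gm)
  expect_equal(which.min(bm$upper - bm$lower), 1L)

  # an exact fit has a zero-width band
  ex <- fit_polynomial(tibble::tibble(x = 1:10, y = 2 * (1:10)), "x", "y")
  bz <- confidence_band(ex, 1:10)
  expect_lt(max(bz$upper - bz$lower), 1e-10)
})

test_that("quadratic never fits worse than linear; improvement needs curvature", {
  line <- withr::with_seed(12, tibble::tibble(
    x = runif(120, 0, 10), y = 3 + 0.8 * runif(120, 0, 10)
  ))
  line$y <- 3 + 0.8 * line$x + withr::with_seed(13, rnorm(120, 0, 0.5))
  cmp <- compare_linear_quadratic(line, "x", "y")
  expect_false(cmp$improved)
  expect_lte(cmp$rmse_quadratic, cmp$rmse_linear)

  curved <- withr::with_seed(14, {
    x <- runif(120, 0, 10)
    tibble::tibble(x = x, y = 1 + x - 0.15 * x^2 + rnorm(120, 0, 0.3))
  })
  cmp2 <- compare_linear_quadratic(curved, "x", "y")
  expect_true(cmp2$improved)
  expect_lt(cmp2$rmse_quadratic, cmp2$rmse_linear)

  # nesting property on arbitrary data
  for (s in 1:5) {
    d <- withr::with_seed(s, tibble::tibble(x = runif(25), y = rnorm(25)))
    cm <- compare_linear_quadratic(d, "x", "y")
    expect_lte(cm$rmse_quadratic, cm$rmse_linear + 1e-12)
  }
})
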