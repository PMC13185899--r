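test_that("noiseless bootstrap concentrates on the true requirement", {
  row <- preset_row("me", "late")
  d <- simulate_preset("me", "late", seed = 70, n = 150, noise_sd = 0)
  b <- bootstrap_requirement(d, "me_intake", n_boot = 25, seed = 70)
  expect_equal(b$n_failed, 0L)
  expect_true(all(abs(b$replicates - row$true_req) / row$true_req < 1e-4))
  expect_lt(b$ci[["upper"]] - b$ci[["lower"]], 1e-3)
})

test_that("bootstrap is deterministic and point estimate ignores n_boot", {
  d <- simulate_preset("dmet", "mid", seed = 71, n = 300)
  b1 <- bootstrap_requirement(d, "dmet_intake", n_boot = 30, seed = 5)
  b2 <- bootstrap_requirement(d, "dmet_intake", n_boot = 30, seed = 5)
  expect_identical(b1$replicates, b2$replicates)
  b3 <- bootstrap_requirement(d, "dmet_intake", n_boot = 45, seed = 5)
  expect_equal(b3$point_estimate, b1$point_estimate, tolerance = 1e-12)
})

test_that("CI endpoints are the (R+1)p order-statistic percentiles", {
  d <- simulate_preset("dlys", "late", seed = 72, n = 300)
  b <- bootstrap_requirement(d, "dlys_intake", n_boot = 40, seed = 9)
  expect_equal(b$ci[["lower"]],
               unname(quantile(b$replicates, 0.025, type = 6)))
  expect_equal(b$ci[["upper"]],
               unname(quantile(b$replicates, 0.975, type = 6)))
  expect_lte(b$ci[["lower"]], b$ci[["upper"]])
  expect_equal(length(b$replicates), b$n_requested - b$n_failed)
})

fake_boot <- function(replicates, point = mean(replicates), label = "x") {
  structure(list(label = label, replicates = replicates,
                 point_estimate = point, n_requested = length(replicates),
                 n_failed = 0L, ci_level = 0.95, p = 0.95),
            class = "boot_req")
}

test_that("phase comparison p-values behave at the boundaries", {
  a <- fake_boot(seq(1, 2, length.out = 50))
  expect_equal(compare_phases(a, a)$p_value, 1)
  expect_false(compare_phases(a, a)$significant)

  b <- fake_boot(seq(3, 4, length.out = 50))  # completely separated
  cmp <- compare_phases(b, a)
  expect_equal(cmp$p_value, 2 / 51)
  expect_true(cmp$significant)

  # floor of the resampling p-value and symmetry under exchange
  expect_gte(cmp$p_value, 2 / (cmp$n_diff + 1))
  expect_equal(compare_phases(a, b)$p_value, cmp$p_value)

  short <- fake_boot(1:10)
  expect_error(compare_phases(short, a), class = "phasereq_inference_error")
})

test_that("mixed distributions give interior p-values", {
  a <- fake_boot(withr::with_seed(1, rnorm(100, 0.3)))
  b <- fake_boot(withr::with_seed(2, rnorm(100, 0)))
  cmp <- compare_phases(a, b)
  expect_gt(cmp$p_value, 2 / 101)
  expect_lt(cmp$p_value, 1)
  expect_equal(cmp$n_diff, 100)
})

test_that("compact letter display covers the canonical cases", {
  est <- c(early = 453.4, mid = 448.9, late = 448.3)
  cmp <- function(sig) tibble::tibble(
    a = c("early", "early", "mid"), b = c("mid", "late", "late"),
    significant = sig
  )
  none <- letter_display(cmp(c(FALSE, FALSE, FALSE)), est)
  expect_equal(none$letters, c("a", "a", "a"))

  all_sig <- letter_display(cmp(c(TRUE, TRUE, TRUE)), est)
  expect_equal(all_sig$group, c("early", "mid", "late"))
  expect_equal(all_sig$letters, c("a", "b", "c"))

  partial <- letter_display(cmp(c(TRUE, TRUE, FALSE)), est)
  expect_equal(partial$letters[partial$group == "early"], "a")
  expect_equal(partial$letters[partial$group == "mid"], "b")
  expect_equal(partial$letters[partial$group == "late"], "b")

  # chain case: early != late but both overlap mid -> mid shares both letters
  chain <- letter_display(cmp(c(FALSE, TRUE, FALSE)), est)
  expect_equal(chain$letters[chain$group == "early"], "a")
  expect_equal(chain$letters[chain$group == "mid"], "ab")
  expect_equal(chain$letters[chain$group == "late"], "b")
})
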