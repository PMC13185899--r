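test_that("CSV round trip reproduces records field-for-field", {
  r <- make_records(5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_flock_records(r, path)
  back <- read_flock_records(path)
  expect_equal(as.data.frame(back[names(r)]), as.data.frame(r))
  expect_true(all(lengths(back$quality_flags) == 0))
})

test_that("missing cells are flagged, never silently coerced", {
  r <- make_records(3)
  r$chicks_per_hen_week[2] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_flock_records(r, path)
  back <- read_flock_records(path)
  expect_identical(back$quality_flags[[2]], "missing:chicks_per_hen_week")
  expect_identical(back$quality_flags[[1]], character(0))

  bad <- readLines(path)
  bad[3] <- sub("^f02,[0-9]+", "f02,forty", bad[3])
  writeLines(bad, path)
  expect_error(read_flock_records(path), class = "phasereq_parse_error")
})

test_that("schema violations name the offending column", {
  r <- make_records(3)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(r, -"age_weeks"), path)
  expect_error(read_flock_records(path), "age_weeks",
               class = "phasereq_schema_error")
  readr::write_csv(dplyr::mutate(r, mystery = 1), path)
  expect_error(read_flock_records(path), "mystery",
               class = "phasereq_schema_error")
})

test_that("intakes are recomputed from composition with correct units", {
  r <- tibble::tibble(
    flock_id = "f1", age_weeks = 30L, feed_intake = 160,
    me_conc = 2800, lys_conc = 0.65, met_conc = 0.45, thr_conc = 0.60,
    dig_lys = 0.85, dig_met = 0.90, dig_thr = 0.80,
    chicks_per_hen_week = 3.2
  )
  out <- compute_intakes(r)
  expect_equal(out$dlys_intake, 160 * 0.65 / 100 * 0.85)  # 0.884 g/d
  expect_equal(out$me_intake, 160 / 1000 * 2800)          # 448 kcal/d
  expect_equal(out$dmet_intake, 160 * 0.45 / 100 * 0.90)
  expect_equal(out$dthr_intake, 160 * 0.60 / 100 * 0.80)

  r2 <- dplyr::mutate(r, dig_met = NA)
  out2 <- compute_intakes(r2)
  expect_true(is.na(out2$dmet_intake))
  expect_true("missing:dig_met" %in% out2$quality_flags[[1]])

  # precomputed intakes preserved unless overwrite is requested
  r3 <- dplyr::mutate(r, me_intake = 999)
  expect_equal(compute_intakes(r3)$me_intake, 999)
  expect_equal(compute_intakes(r3, overwrite = TRUE)$me_intake, 448)

  expect_error(compute_intakes(dplyr::mutate(r, feed_intake = -1)),
               class = "phasereq_validation_error")
})

test_that("range filtering rejects with machine-readable reasons", {
  r <- make_records(4)
  r$age_weeks <- c(30L, 70L, 40L, 55L)
  res <- filter_records(r)
  expect_equal(nrow(res$kept), 3)
  expect_equal(res$rejected$reject_reason, "range:age_weeks")
  expect_equal(res$counts$n_kept + res$counts$n_rejected, 4)
  # kept records are unchanged
  expect_equal(as.data.frame(res$kept[names(r)]),
               as.data.frame(r[r$age_weeks != 70, ]))

  clean <- filter_records(make_records(6))
  expect_equal(nrow(clean$rejected), 0)
})

test_that("per-phase IQR fence isolates a single extreme response", {
  r <- make_records(100, seed = 9)
  r$age_weeks <- rep(40L, 100)                  # all mid phase
  r$chicks_per_hen_week <- withr::with_seed(9, runif(100, 4.0, 4.6))
  r$chicks_per_hen_week[57] <- 6.9              # inside hard bounds
  # independent Tukey fence on the same values
  q <- unname(quantile(r$chicks_per_hen_week, c(0.25, 0.75), type = 7))
  expect_gt(6.9, q[2] + 1.5 * (q[2] - q[1]))

  flagged <- filter_records(r, filter_config(iqr_action = "flag"))
  expect_equal(nrow(flagged$kept), 100)
  expect_true("iqr:chicks_per_hen_week" %in% flagged$kept$quality_flags[[57]])

  rejected <- filter_records(r, filter_config(iqr_action = "reject"))
  expect_equal(nrow(rejected$kept), 99)
  expect_match(rejected$rejected$reject_reason, "iqr:chicks_per_hen_week")
})

test_that("phase assignment partitions ages 26-62 at the documented cuts", {
  expect_equal(as.character(assign_phase(c(26, 32))), c("early", "early"))
  expect_equal(as.character(assign_phase(c(33, 50))), c("mid", "mid"))
  expect_equal(as.character(assign_phase(c(51, 62))), c("late", "late"))
  expect_error(assign_phase(25), class = "phasereq_range_error")
  expect_error(assign_phase(63), class = "phasereq_range_error")
  # every age in range maps to exactly one phase
  ph <- assign_phase(26:62)
  expect_false(any(is.na(ph)))
  expect_equal(as.vector(table(ph)[phase_levels()]), c(7, 18, 12))
})
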