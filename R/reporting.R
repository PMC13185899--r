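# Reporting: percent-change comparisons against reference intakes,
# requirement tables with letters, and notched-boxplot statistics.

#' Bundled reference requirement values
#'
#' Breeder-guideline and literature peak-production intakes used for
#' percent-change comparisons: Ross 308 parent-stock recommendations at
#' peak (ME 468 kcal/d, dLys 1.036, dMet 0.635, dThr 0.919 g/d) and
#' literature optima for egg mass and fertility at peak lay (dLys
#' 0.916, dMet 0.424, dThr 0.613 g/d).
#'
#' @return A tibble with columns `source`, `nutrient`, `phase`,
#'   `value`, `units`.
#' @export
reference_values <- function() {
  tibble::tribble(
    ~source, ~nutrient, ~phase, ~value, ~units,
    "ross308",    "me",   "mid", 468,    "kcal/d",
    "ross308",    "dlys", "mid", 1.036,  "g/d",
    "ross308",    "dmet", "mid", 0.635,  "g/d",
    "ross308",    "dthr", "mid", 0.919,  "g/d",
    "literature", "dlys", "mid", 0.916,  "g/d",
    "literature", "dmet", "mid", 0.424,  "g/d",
    "literature", "dthr", "mid", 0.613,  "g/d"
  )
}

#' Percent change of a value relative to a reference
#'
#' `100 * (value - reference) / reference`, rounded to `digits`
#' decimals (1 by default, matching the reporting convention;
#' `digits = NA` suppresses rounding).
#'
#' @param value positive numeric vector.
#' @param reference positive numeric vector (recycled).
#' @param digits decimals for rounding, default 1.
#' @return Percent change(s).
#' @export
#' @examples
#' percent_change(1.03, 0.95)  # 8.4
percent_change <- function(value, reference, digits = 1) {
  if (any(reference <= 0)) {
    abort("`reference` must be positive.",
          class = "phasereq_validation_error")
  }
  out <- 100 * (value - reference) / reference
  if (!is.na(digits)) out <- round(out, digits)
  out
}

#' Assemble the requirement table
#'
#' One row per nutrient-phase combination with the point estimate,
#' percentile CI bounds taken verbatim from the bootstrap objects, and
#' compact letters from the per-nutrient phase comparisons. A missing
#' combination yields an absent row, not a failure.
#'
#' @param boots named list of [bootstrap_requirement()] objects; names
#'   `"<nutrient>:<phase>"`.
#' @param letters optional tibble from [letter_display()] results bound
#'   together with a `nutrient` column (columns `nutrient`, `group`,
#'   `letters`).
#' @return A tibble: `nutrient`, `phase`, `req`, `ci_lo`, `ci_hi`,
#'   `n_replicates`, `n_failed`, `letter`.
#' @export
requirement_table <- function(boots, letters = NULL) {
  rows <- purrr::imap(boots, function(b, nm) {
    key <- strsplit(nm, ":", fixed = TRUE)[[1]]
    dplyr::mutate(tidy(b), nutrient = key[1], phase = key[2],
                  .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::select(out, "nutrient", "phase", "req", "ci_lo", "ci_hi",
                       "n_replicates", "n_failed")
  if (!is.null(letters) && nrow(letters) == 0) letters <- NULL
  if (!is.null(letters)) {
    out <- dplyr::left_join(
      out, dplyr::select(letters, "nutrient", phase = "group",
                         letter = "letters"),
      by = c("nutrient", "phase")
    )
  } else {
    out$letter <- NA_character_
  }
  out$phase <- factor(out$phase, levels = phase_levels())
  dplyr::arrange(out, .data$nutrient, .data$phase)
}

#' Notched-boxplot statistics
#'
#' Quantities behind the modified boxplots used to compare bootstrap
#' requirement distributions: type-7 quartiles; whiskers at the most
#' extreme observations within 1.5 IQR of the quartiles; the notch
#' `median +/- 1.57 * IQR / sqrt(n)` (an approximate 95% CI for the
#' median); and the mean with a seeded percentile-bootstrap CI.
#'
#' @param samples numeric vector, at least 5 values.
#' @param mean_ci_boot bootstrap replicates for the mean CI (default
#'   1000).
#' @param level CI level for the mean (default 0.95).
#' @param seed integer seed for the mean bootstrap.
#' @return A one-row tibble: `n`, `median`, `q1`, `q3`, `whisker_lo`,
#'   `whisker_hi`, `notch_lo`, `notch_hi`, `mean`, `mean_ci_lo`,
#'   `mean_ci_hi`.
#' @export
#' @examples
#' boxplot_stats(1:9)
boxplot_stats <- function(samples, mean_ci_boot = 1000, level = 0.95,
                          seed = 1L) {
  samples <- samples[!is.na(samples)]
  n <- length(samples)
  if (n < 5) {
    abort("Need at least 5 samples for boxplot statistics.",
          class = "phasereq_size_error")
  }
  q <- quartiles(samples)
  iqr <- q[3] - q[1]
  in_lo <- samples[samples >= q[1] - 1.5 * iqr]
  in_hi <- samples[samples <= q[3] + 1.5 * iqr]
  notch_half <- 1.57 * iqr / sqrt(n)
  means <- with_seed(seed, {
    vapply(seq_len(mean_ci_boot),
           function(i) mean(sample(samples, n, replace = TRUE)),
           numeric(1))
  })
  tibble::tibble(
    n = n, median = q[2], q1 = q[1], q3 = q[3],
    whisker_lo = min(in_lo), whisker_hi = max(in_hi),
    notch_lo = q[2] - notch_half, notch_hi = q[2] + notch_half,
    mean = mean(samples),
    mean_ci_lo = unname(quantile(means, (1 - level) / 2, type = 7)),
    mean_ci_hi = unname(quantile(means, (1 + level) / 2, type = 7))
  )
}
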