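# Flock-week records: the tabular data model, CSV round trip, intake
# recalculation and phase stratification.

# Column schemas for the two supported CSV layouts.
schema_intakes <- c(
  "flock_id", "age_weeks", "me_intake", "dlys_intake", "dmet_intake",
  "dthr_intake", "chicks_per_hen_week"
)
schema_composition <- c(
  "flock_id", "age_weeks", "feed_intake", "me_conc", "lys_conc", "met_conc",
  "thr_conc", "dig_lys", "dig_met", "dig_thr", "chicks_per_hen_week"
)

intake_cols <- c("me_intake", "dlys_intake", "dmet_intake", "dthr_intake")

#' Production phase boundaries
#'
#' The three production phases of a broiler breeder laying cycle, as
#' closed intervals of hen age in weeks: early (26-32), mid/peak (33-50)
#' and late (51-62). The intervals are disjoint and together cover ages
#' 26 to 62.
#'
#' @return A tibble with columns `phase`, `age_min`, `age_max`.
#' @export
#' @examples
#' phase_table()
phase_table <- function() {
  tibble::tibble(
    phase = factor(c("early", "mid", "late"), levels = phase_levels()),
    age_min = c(26L, 33L, 51L),
    age_max = c(32L, 50L, 62L)
  )
}

phase_levels <- function() c("early", "mid", "late")

#' Assign production phase from hen age
#'
#' Maps age in weeks to the production phase: 26-32 weeks is `early`,
#' 33-50 is `mid`, 51-62 is `late`.
#'
#' @param age_weeks integer vector of hen ages in weeks.
#' @return Factor with levels `early`, `mid`, `late`.
#' @export
#' @examples
#' assign_phase(c(26, 40, 62))
assign_phase <- function(age_weeks) {
  if (any(!is.finite(age_weeks) | age_weeks < 26 | age_weeks > 62)) {
    bad <- age_weeks[!is.finite(age_weeks) | age_weeks < 26 | age_weeks > 62]
    abort(
      paste0("age_weeks outside the studied range [26, 62]: ",
             paste(utils::head(bad, 5), collapse = ", ")),
      class = "phasereq_range_error"
    )
  }
  pt <- phase_table()
  idx <- findInterval(age_weeks, c(pt$age_min, 63L))
  factor(phase_levels()[idx], levels = phase_levels())
}

#' Add a phase column to flock-week records
#'
#' @param records tibble of flock-week records with an `age_weeks` column.
#' @return The input with a `phase` factor column.
#' @export
add_phase <- function(records) {
  dplyr::mutate(tibble::as_tibble(records),
                phase = assign_phase(.data$age_weeks))
}

flag_name <- function(col) paste0("missing:", col)

# Ensure a list-column of character flag vectors.
init_flags <- function(n) replicate(n, character(0), simplify = FALSE)

add_flag <- function(flags, where, code) {
  flags[where] <- lapply(flags[where], function(f) union(f, code))
  flags
}

#' Read flock-week records from CSV
#'
#' Reads one of the two documented schemas. `intakes` mode carries
#' precomputed daily nutrient intakes (ME in kcal/bird/day, digestible
#' amino acids in g/bird/day); `composition` mode carries feed intake
#' (g/bird/day), dietary concentrations (ME in kcal/kg, amino acids in
#' g per 100 g feed) and digestibility coefficients, from which intakes
#' are recalculated with [compute_intakes()]. Empty cells become `NA`
#' and are recorded in the `quality_flags` list-column as
#' `"missing:<column>"`; non-numeric text in a numeric column is an
#' error, never a silent `NA`.
#'
#' @param path CSV file path (UTF-8, header row required).
#' @param schema_mode `"intakes"` or `"composition"`.
#' @return A tibble with one row per data row plus a `quality_flags`
#'   list-column of character vectors.
#' @export
read_flock_records <- function(path, schema_mode = c("intakes", "composition")) {
  schema_mode <- match.arg(schema_mode)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "phasereq_io_error")
  }
  required <- if (schema_mode == "intakes") schema_intakes else schema_composition
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               name_repair = "minimal"))
  missing_cols <- setdiff(required, hdr)
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "phasereq_schema_error")
  }
  unknown <- setdiff(hdr, required)
  if (length(unknown) > 0) {
    abort(paste0("Unknown column(s) for ", schema_mode, " mode: ",
                 paste(unknown, collapse = ", ")),
          class = "phasereq_schema_error")
  }
  spec <- readr::cols(
    flock_id = readr::col_character(),
    age_weeks = readr::col_double(),
    .default = readr::col_double()
  )
  df <- suppressWarnings(
    readr::read_csv(path, col_types = spec, show_col_types = FALSE)
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(
      paste0("Non-numeric or malformed cell(s), e.g. row ", probs$row[1],
             " col ", probs$col[1], "; refusing silent coercion."),
      class = "phasereq_parse_error"
    )
  }
  df <- df[required]
  flags <- init_flags(nrow(df))
  for (col in setdiff(required, "flock_id")) {
    flags <- add_flag(flags, is.na(df[[col]]), flag_name(col))
  }
  df$quality_flags <- flags
  validate_records(df)
  tibble::as_tibble(df)
}

#' Write flock-week records to CSV
#'
#' Inverse of [read_flock_records()]: the `quality_flags` list-column is
#' dropped (flags are derivable from missingness), every other field is
#' written verbatim, so a read of the written file reproduces the
#' records field-for-field.
#'
#' @param records tibble of flock-week records.
#' @param path output CSV path.
#' @param schema_mode `"intakes"` or `"composition"`.
#' @return `path`, invisibly.
#' @export
write_flock_records <- function(records, path,
                                schema_mode = c("intakes", "composition")) {
  schema_mode <- match.arg(schema_mode)
  required <- if (schema_mode == "intakes") schema_intakes else schema_composition
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Records lack column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "phasereq_schema_error")
  }
  readr::write_csv(records[required], path, na = "")
  invisible(path)
}

# Hard invariants of the data model; violations are data errors, not
# quality flags.
validate_records <- function(records) {
  chk <- function(col, ok, what) {
    if (col %in% names(records)) {
      v <- records[[col]]
      bad <- !is.na(v) & !ok(v)
      if (any(bad)) {
        abort(paste0("Invalid ", col, ": ", what, " (first bad value ",
                     format(v[which(bad)[1]]), ")"),
              class = "phasereq_validation_error")
      }
    }
  }
  nonneg <- function(v) v >= 0
  chk("age_weeks", nonneg, "must be >= 0")
  for (col in c(intake_cols, "feed_intake", "me_conc", "lys_conc",
                "met_conc", "thr_conc", "chicks_per_hen_week")) {
    chk(col, nonneg, "must be >= 0")
  }
  for (col in c("dig_lys", "dig_met", "dig_thr")) {
    chk(col, function(v) v >= 0 & v <= 1, "digestibility must lie in [0, 1]")
  }
  invisible(records)
}

#' Recompute daily nutrient intakes from dietary composition
#'
#' Digestible amino-acid intakes are recalculated from daily feed intake,
#' dietary concentration and the digestibility coefficient:
#' `dAA_intake [g/d] = feed_intake [g/d] x (AA_conc [g/100 g] / 100) x dig_AA`.
#' ME intake is computed directly from feed intake:
#' `me_intake [kcal/d] = feed_intake [g/d] / 1000 x me_conc [kcal/kg]`.
#' A missing concentration or digestibility coefficient leaves the
#' corresponding intake missing and adds a `"missing:<column>"` flag.
#' Precomputed intakes already present are preserved unless
#' `overwrite = TRUE`.
#'
#' @param records tibble in composition layout (see [read_flock_records()]).
#' @param overwrite replace existing intake columns? Default `FALSE`.
#' @return The records with `me_intake`, `dlys_intake`, `dmet_intake`,
#'   `dthr_intake` columns filled in and flags updated.
#' @export
#' @examples
#' r <- tibble::tibble(flock_id = "f1", age_weeks = 30L, feed_intake = 160,
#'                     me_conc = 2800, lys_conc = 0.65, met_conc = 0.45,
#'                     thr_conc = 0.60, dig_lys = 0.85, dig_met = 0.90,
#'                     dig_thr = 0.80, chicks_per_hen_week = 3.2)
#' compute_intakes(r)[, c("me_intake", "dlys_intake")]
compute_intakes <- function(records, overwrite = FALSE) {
  records <- tibble::as_tibble(records)
  validate_records(records)
  if (!"quality_flags" %in% names(records)) {
    records$quality_flags <- init_flags(nrow(records))
  }
  aa <- list(
    dlys_intake = c(conc = "lys_conc", dig = "dig_lys"),
    dmet_intake = c(conc = "met_conc", dig = "dig_met"),
    dthr_intake = c(conc = "thr_conc", dig = "dig_thr")
  )
  feed <- records$feed_intake
  if (is.null(feed)) {
    abort("`feed_intake` is required to compute intakes.",
          class = "phasereq_validation_error")
  }
  fill <- function(records, target, value, needed_cols) {
    existing <- records[[target]]
    if (is.null(existing)) existing <- rep(NA_real_, nrow(records))
    take <- if (overwrite) rep(TRUE, nrow(records)) else is.na(existing)
    existing[take] <- value[take]
    records[[target]] <- existing
    for (col in needed_cols) {
      records$quality_flags <- add_flag(
        records$quality_flags, take & is.na(records[[col]]), flag_name(col)
      )
    }
    records
  }
  records <- fill(records, "me_intake", feed / 1000 * records$me_conc,
                  c("feed_intake", "me_conc"))
  for (target in names(aa)) {
    cols <- aa[[target]]
    value <- feed * (records[[cols["conc"]]] / 100) * records[[cols["dig"]]]
    records <- fill(records, target, value,
                    c("feed_intake", cols["conc"], cols["dig"]))
  }
  records
}

#' Range and outlier filter configuration
#'
#' Hard physiological bounds per variable plus an optional per-phase
#' Tukey fence (quartiles +/- `iqr_multiplier` x IQR). The published
#' analysis screened outliers by graphical inspection against
#' physiologically reasonable ranges; this configuration is the
#' reproducible surrogate for that manual step. Default bounds are
#' deliberately wide and config-exposed, not asserted facts.
#'
#' @param bounds named list of `c(lower, upper)` bounds per column.
#' @param iqr_multiplier positive multiplier for the Tukey fence
#'   (default 1.5).
#' @param iqr_action `"flag"` (default) or `"reject"` for IQR outliers.
#' @param iqr_vars columns screened by the IQR fence.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(bounds = NULL,
                          iqr_multiplier = 1.5,
                          iqr_action = c("flag", "reject"),
                          iqr_vars = c(intake_cols, "chicks_per_hen_week")) {
  iqr_action <- match.arg(iqr_action)
  defaults <- list(
    age_weeks = c(26, 62),
    me_intake = c(200, 600),
    dlys_intake = c(0.2, 2.0),
    dmet_intake = c(0.1, 1.5),
    dthr_intake = c(0.1, 1.8),
    chicks_per_hen_week = c(0, 7)
  )
  bounds <- modifyList(defaults, bounds %||% list())
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2 || !(b[1] < b[2])) {
      abort(paste0("Bound for ", nm, " must satisfy lower < upper."),
            class = "phasereq_validation_error")
    }
  }
  if (iqr_multiplier <= 0) {
    abort("`iqr_multiplier` must be positive.",
          class = "phasereq_validation_error")
  }
  structure(list(bounds = bounds, iqr_multiplier = iqr_multiplier,
                 iqr_action = iqr_action, iqr_vars = iqr_vars),
            class = "filter_config")
}

#' Partition records into kept and rejected sets
#'
#' Applies, in order: (1) missing-value screening of the required
#' analysis fields (any nutrient intake and the response), (2) hard
#' physiological bounds from the configuration, and (3) an optional
#' per-phase Tukey IQR fence, flag-only by default. Filtering never
#' alters field values of kept records and never raises on data
#' content; `kept` plus `rejected` is a partition of the input.
#'
#' @param records tibble of flock-week records.
#' @param config a [filter_config()].
#' @param required_fields fields that must be non-missing; default
#'   `age_weeks` and `chicks_per_hen_week` plus at least one intake.
#' @return A list with tibbles `kept`, `rejected` (with a
#'   `reject_reason` column) and a `counts` summary tibble.
#' @export
filter_records <- function(records, config = filter_config(),
                           required_fields = c("age_weeks",
                                               "chicks_per_hen_week")) {
  records <- tibble::as_tibble(records)
  n <- nrow(records)
  if (!"quality_flags" %in% names(records)) {
    records$quality_flags <- init_flags(n)
  }
  reasons <- rep("", n)
  add_reason <- function(reasons, where, code) {
    sep <- ifelse(reasons[where] == "", "", ";")
    reasons[where] <- paste0(reasons[where], sep, code)
    reasons
  }
  for (col in required_fields) {
    miss <- if (col %in% names(records)) is.na(records[[col]]) else rep(TRUE, n)
    reasons <- add_reason(reasons, miss, paste0("missing:", col))
  }
  has_intake <- Reduce(`|`, lapply(intake_cols, function(col) {
    if (col %in% names(records)) !is.na(records[[col]]) else rep(FALSE, n)
  }))
  reasons <- add_reason(reasons, !has_intake, "missing:any_intake")
  for (col in intersect(names(config$bounds), names(records))) {
    b <- config$bounds[[col]]
    v <- records[[col]]
    out <- !is.na(v) & (v < b[1] | v > b[2])
    reasons <- add_reason(reasons, out, paste0("range:", col))
  }
  # per-phase Tukey fence on records that survived the hard screens
  in_play <- reasons == ""
  phase_ok <- "age_weeks" %in% names(records) &
    all(!is.na(records$age_weeks[in_play]))
  if (phase_ok && any(in_play)) {
    phase <- rep(NA_character_, n)
    phase[in_play] <- as.character(assign_phase(records$age_weeks[in_play]))
    for (col in intersect(config$iqr_vars, names(records))) {
      for (ph in phase_levels()) {
        sel <- in_play & !is.na(phase) & phase == ph & !is.na(records[[col]])
        if (sum(sel) >= 4) {
          q <- quartiles(records[[col]][sel])
          fence <- config$iqr_multiplier * (q[3] - q[1])
          out <- sel & (records[[col]] < q[1] - fence |
                          records[[col]] > q[3] + fence)
          records$quality_flags <- add_flag(records$quality_flags, out,
                                            paste0("iqr:", col))
          if (config$iqr_action == "reject") {
            reasons <- add_reason(reasons, out, paste0("iqr:", col))
          }
        }
      }
    }
  }
  keep <- reasons == ""
  rejected <- records[!keep, , drop = FALSE]
  rejected$reject_reason <- reasons[!keep]
  list(
    kept = records[keep, , drop = FALSE],
    rejected = rejected,
    counts = tibble::tibble(n_input = n, n_kept = sum(keep),
                            n_rejected = sum(!keep))
  )
}
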