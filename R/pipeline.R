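# End-to-end orchestration: simulate or ingest records, filter, stratify
# by phase, fit baselines and tanh curves, derive requirements, bootstrap,
# compare phases, and assemble report tables. A run is a pure function of
# (input data, config, seed).

#' Default pipeline configuration
#'
#' @param seed master integer seed for every stochastic stage.
#' @param nutrients subset of `c("me", "dlys", "dmet", "dthr")`.
#' @param n_boot bootstrap replicates per nutrient-phase fit.
#' @param p requirement response fraction (default 0.95).
#' @param ci_level confidence level (default 0.95).
#' @param n_restarts multi-starts for each full-data tanh fit.
#' @param filters list: `enabled` (default TRUE), optional `bounds`,
#'   `iqr_multiplier`, `iqr_action` passed to [filter_config()].
#' @param data list: either `source = "simulate"` (with optional
#'   `presets` tibble, defaulting to [scenario_presets()]) or
#'   `source = "csv"` with `path` and `schema_mode`.
#' @return A config list, also writable/readable as YAML.
#' @export
default_config <- function(seed = 1L,
                           nutrients = c("me", "dlys", "dmet", "dthr"),
                           n_boot = 100L, p = 0.95, ci_level = 0.95,
                           n_restarts = 10L,
                           filters = list(enabled = TRUE),
                           data = list(source = "simulate")) {
  list(seed = as.integer(seed), nutrients = nutrients,
       n_boot = as.integer(n_boot), p = p, ci_level = ci_level,
       n_restarts = as.integer(n_restarts), filters = filters, data = data)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  modifyList(default_config(), config)
}

#' Run the full requirement-estimation pipeline
#'
#' Executes simulate/ingest -> filter -> phase split -> baseline
#' regressions -> tanh fits -> requirements -> bootstrap -> phase
#' comparisons -> report tables. Idempotent given the config and seed;
#' every output carries provenance (config hash, seed, package
#' version). Any stage error aborts with the stage name.
#'
#' @param config a list from [default_config()], a YAML file path, or a
#'   partial list merged over the defaults.
#' @param out_dir optional directory; when given, report tables are
#'   written as CSV and the run summary as JSON.
#' @return An object of class `phasereq_run`: tibbles `requirements`,
#'   `baseline`, `comparisons`, `letters`, `percent_changes`,
#'   `boxplots`, the list `boots` of bootstrap objects, `config`, and
#'   `provenance`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  config <- read_pipeline_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "phasereq_pipeline_error", parent = e)
    })
  }

  presets <- NULL
  records <- stage("data", {
    if (identical(config$data$source, "csv")) {
      r <- read_flock_records(config$data$path,
                              config$data$schema_mode %||% "intakes")
      if (identical(config$data$schema_mode, "composition")) {
        r <- compute_intakes(r)
      }
      r
    } else {
      presets <- config$data$presets %||% scenario_presets()
      presets <- presets[presets$nutrient %in% config$nutrients, ]
      simulate_scenarios(presets, seed = config$seed)
    }
  })

  filtered <- stage("filter", {
    if (isTRUE(config$filters$enabled)) {
      fc <- filter_config(
        bounds = config$filters$bounds,
        iqr_multiplier = config$filters$iqr_multiplier %||% 1.5,
        iqr_action = config$filters$iqr_action %||% "flag"
      )
      filter_records(records, fc)
    } else {
      list(kept = records, rejected = records[0, ],
           counts = tibble::tibble(n_input = nrow(records),
                                   n_kept = nrow(records), n_rejected = 0L))
    }
  })
  kept <- stage("phase", add_phase(filtered$kept))

  jobs <- tidyr::expand_grid(nutrient = config$nutrients,
                             phase = phase_levels())
  seeds <- derive_seeds(config$seed, nrow(jobs))

  boots <- list()
  baseline_rows <- list()
  box_rows <- list()
  for (i in seq_len(nrow(jobs))) {
    nut <- jobs$nutrient[i]
    ph <- jobs$phase[i]
    col <- paste0(nut, "_intake")
    d <- kept[kept$phase == ph & !is.na(kept[[col]]), ]
    if ("nutrient" %in% names(d)) d <- d[d$nutrient == nut, ]
    if (nrow(d) < 5) next
    key <- paste0(nut, ":", ph)
    baseline_rows[[key]] <- stage(paste0("baseline:", key), {
      lin <- fit_polynomial(d, col, degree = 1)
      dplyr::mutate(compare_linear_quadratic(d, col),
                    nutrient = nut, phase = ph, n = lin$n, r = lin$r,
                    .before = 1)
    })
    boots[[key]] <- stage(paste0("bootstrap:", key), {
      bootstrap_requirement(
        d, col, n_boot = config$n_boot, p = config$p,
        ci_level = config$ci_level, seed = seeds[i],
        control = tanh_control(n_restarts = config$n_restarts,
                               seed = seeds[i]),
        label = key
      )
    })
    box_rows[[key]] <- dplyr::mutate(
      boxplot_stats(boots[[key]]$replicates, seed = seeds[i]),
      nutrient = nut, phase = ph, .before = 1
    )
  }
  if (length(boots) == 0) {
    abort("Pipeline produced no fit-able nutrient-phase subsets.",
          class = "phasereq_pipeline_error")
  }

  comparisons <- list()
  letters_rows <- list()
  for (nut in unique(jobs$nutrient)) {
    keys <- paste0(nut, ":", phase_levels())
    keys <- keys[keys %in% names(boots)]
    if (length(keys) < 2) next
    pairs <- utils::combn(keys, 2, simplify = FALSE)
    cmp <- dplyr::bind_rows(lapply(pairs, function(pr) {
      compare_phases(boots[[pr[1]]], boots[[pr[2]]])
    }))
    cmp$a <- sub("^.*:", "", cmp$a)
    cmp$b <- sub("^.*:", "", cmp$b)
    comparisons[[nut]] <- dplyr::mutate(cmp, nutrient = nut, .before = 1)
    if (length(keys) >= 2) {
      est <- setNames(
        vapply(keys, function(k) boots[[k]]$point_estimate, numeric(1)),
        sub("^.*:", "", keys)
      )
      letters_rows[[nut]] <- dplyr::mutate(letter_display(cmp, est),
                                           nutrient = nut, .before = 1)
    }
  }
  comparisons <- dplyr::bind_rows(comparisons)
  letters_tbl <- dplyr::bind_rows(letters_rows)

  req_tbl <- requirement_table(boots, letters_tbl)
  pct <- stage("percent_change", pipeline_percent_changes(req_tbl))

  provenance <- list(
    seed = config$seed,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("phasereq")),
    n_input = filtered$counts$n_input,
    n_kept = filtered$counts$n_kept
  )
  run <- structure(
    list(requirements = req_tbl,
         baseline = dplyr::bind_rows(baseline_rows),
         comparisons = comparisons, letters = letters_tbl,
         percent_changes = pct,
         boxplots = dplyr::bind_rows(box_rows),
         boots = boots, filtered_counts = filtered$counts,
         presets = presets, config = config, provenance = provenance),
    class = "phasereq_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# Discussion-style comparisons: mid-phase amino-acid increases relative
# to early phase, and mid-phase estimates against bundled references.
pipeline_percent_changes <- function(req_tbl) {
  refs <- reference_values()
  rows <- list()
  for (nut in unique(req_tbl$nutrient)) {
    sub <- req_tbl[req_tbl$nutrient == nut, ]
    mid <- sub$req[sub$phase == "mid"]
    early <- sub$req[sub$phase == "early"]
    if (length(mid) == 1 && length(early) == 1) {
      rows[[paste0(nut, ":mid_vs_early")]] <- tibble::tibble(
        nutrient = nut, comparison = "mid_vs_early",
        value = mid, reference = early,
        pct = percent_change(mid, early)
      )
    }
    for (src in unique(refs$source)) {
      ref <- refs$value[refs$source == src & refs$nutrient == nut]
      if (length(mid) == 1 && length(ref) == 1) {
        rows[[paste0(nut, ":mid_vs_", src)]] <- tibble::tibble(
          nutrient = nut, comparison = paste0("mid_vs_", src),
          value = mid, reference = ref,
          pct = percent_change(mid, ref)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$requirements, file.path(out_dir, "requirements.csv"))
  readr::write_csv(run$baseline, file.path(out_dir, "baseline.csv"))
  readr::write_csv(run$comparisons, file.path(out_dir, "comparisons.csv"))
  readr::write_csv(run$percent_changes,
                   file.path(out_dir, "percent_changes.csv"))
  readr::write_csv(run$boxplots, file.path(out_dir, "boxplot_stats.csv"))
  replicates <- purrr::imap(run$boots, function(b, nm) {
    tibble::tibble(label = nm, replicate = seq_along(b$replicates),
                   req = b$replicates)
  })
  readr::write_csv(dplyr::bind_rows(replicates),
                   file.path(out_dir, "bootstrap_replicates.csv"))
  jsonlite::write_json(
    list(provenance = run$provenance, config = run$config,
         requirements = run$requirements),
    file.path(out_dir, "run.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}

#' @export
print.phasereq_run <- function(x, ...) {
  cat("phasereq pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat("  records kept: ", x$filtered_counts$n_kept, "/",
      x$filtered_counts$n_input, "\n", sep = "")
  print(x$requirements)
  invisible(x)
}
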