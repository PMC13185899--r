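# Shared fixtures: tiny record tables and preset-driven simulations.

make_records <- function(n = 3, seed = 42) {
  withr::with_seed(seed, tibble::tibble(
    flock_id = sprintf("f%02d", seq_len(n)),
    age_weeks = sample(26:62, n, replace = TRUE),
    me_intake = runif(n, 400, 470),
    dlys_intake = runif(n, 0.7, 1.1),
    dmet_intake = runif(n, 0.4, 0.75),
    dthr_intake = runif(n, 0.5, 0.9),
    chicks_per_hen_week = runif(n, 2, 5.5)
  ))
}

preset_row <- function(nutrient, phase) {
  pr <- scenario_presets()
  pr[pr$nutrient == nutrient & pr$phase == phase, ]
}

simulate_preset <- function(nutrient, phase, seed, n = NULL, noise_sd = NULL) {
  row <- preset_row(nutrient, phase)
  simulate_phase(
    n = n %||% row$n, phase = phase,
    params = tanh_params(row$A, row$b, row$c, row$B),
    intake_range = c(row$x_lo, row$x_hi),
    noise_sd = noise_sd %||% row$noise_sd,
    nutrient = paste0(nutrient, "_intake"),
    seed = seed
  )
}

`%||%` <- rlang::`%||%`
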