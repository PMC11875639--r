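# Virtual-participant simulator. A simulated trace pursues the target
# line through a first-order behavioral model -- fractional tracking
# lag, multiplicative gain, band-limited (~1 Hz) tracking error whose
# amplitude decays exponentially across trials toward an asymptote,
# white sensor noise -- then passes through the device model:
# quantization to the force resolution and clipping to the force range.

#' Grip-device measurement model
#'
#' @return Named list: `spring_constant` (N/m), `force_range` (kg),
#'   `resolution` (kg), `delta_t` (s).
#' @export
device_model <- function() {
  list(spring_constant = 4.82e2, force_range = c(0, 0.5),
       resolution = 1.6e-3, delta_t = 0.1)
}

#' Spring deformation under an applied grip force
#'
#' Linear spring: `x = m * g0 / k`, reported in millimetres
#' (`g0 = 9.80665 m/s^2`).
#'
#' @param applied_force Force in kg; must lie within the device range.
#' @param device Device description ([device_model()]).
#' @return Deformation in mm.
#' @examples
#' deformation(4.92e-2)  # ~1 mm
#' @export
deformation <- function(applied_force, device = device_model()) {
  rng <- device$force_range
  if (any(applied_force < rng[1] | applied_force > rng[2])) {
    stop("applied force outside the device range [", rng[1], ", ", rng[2],
         "] kg")
  }
  applied_force * 9.80665 / device$spring_constant * 1000
}

#' Quantize and clip a force trace to the device output grid
#'
#' Clips to the measurable range, then rounds to the nearest multiple
#' of the device resolution, so every emitted value is representable.
#'
#' @param x Forces in kg.
#' @param device Device description.
#' @return Quantized, clipped forces (kg).
#' @export
quantize_force <- function(x, device = device_model()) {
  rng <- device$force_range
  x <- pmin(pmax(x, rng[1]), rng[2])
  round(x / device$resolution) * device$resolution
}

# Unit-variance band-limited Gaussian noise: white noise smoothed by a
# Gaussian kernel (sd sigma_t seconds; ~1 Hz bandwidth at the default),
# normalized so each sample is marginally N(0, 1). Consumes
# n + 2*half_width white draws from the current RNG stream.
colored_noise <- function(n, sigma_t = 0.15, delta_t = 0.1) {
  sigma_s <- sigma_t / delta_t
  half <- ceiling(4 * sigma_s)
  w <- stats::dnorm(seq(-half, half), sd = sigma_s)
  w <- w / sqrt(sum(w^2))
  white <- stats::rnorm(n + 2L * half)
  # convolve(type = "filter") keeps the fully-overlapped region
  stats::convolve(white, w, type = "filter")
}

trial_error_scale <- function(e0, einf, r, trial_index) {
  einf + (e0 - einf) * r^(trial_index - 1)
}

#' Simulate one tracked trial
#'
#' The measured trace is the target delayed by `lag` samples (linear
#' interpolation, edge-held), scaled by `gain`, plus band-limited
#' tracking error with per-half amplitude
#' `e_t = einf + (e0 - einf) * r^(t-1)` at trial `t`, plus white noise,
#' quantized and clipped by the device model.
#'
#' @param spec `task_spec` the trial pursues.
#' @param params Participant parameters: one-row data.frame or list
#'   with `lag` (samples), `gain`, `noise_sd` (kg), and per half
#'   `e0_ran`, `einf_ran`, `r_ran`, `e0_rep`, `einf_rep`, `r_rep`.
#' @param trial_index Trial number 1..50.
#' @param seed Integer seed; the trace is deterministic given the seed.
#' @param device Device description.
#' @return `trial_record`: list with `trial_index`, `block_index`,
#'   `task_id`, `measured` (230 forces, kg).
#' @export
simulate_trial <- function(spec, params, trial_index, seed,
                           device = device_model()) {
  stopifnot(inherits(spec, "task_spec"), trial_index >= 1)
  check_participant_params(params)
  base <- lag_gain_target(spec$samples, params$lag, params$gain)
  measured <- with_seed(seed, {
    trial_noise(base, spec, params, trial_index, device)
  })
  structure(
    list(trial_index = as.integer(trial_index),
         block_index = as.integer(ceiling(trial_index / 5)),
         task_id = spec$task_id, measured = measured),
    class = "trial_record"
  )
}

check_participant_params <- function(params) {
  need <- c("lag", "gain", "noise_sd", "e0_ran", "einf_ran", "r_ran",
            "e0_rep", "einf_rep", "r_rep")
  miss <- setdiff(need, names(params))
  if (length(miss)) {
    stop("participant params missing field(s): ", paste(miss, collapse = ", "))
  }
  stopifnot(params$lag >= 0, params$noise_sd >= 0,
            params$e0_ran >= 0, params$einf_ran >= 0,
            params$e0_rep >= 0, params$einf_rep >= 0,
            params$r_ran > 0, params$r_ran <= 1,
            params$r_rep > 0, params$r_rep <= 1)
  invisible(params)
}

lag_gain_target <- function(samples, lag, gain) {
  n <- length(samples)
  if (lag > 0) {
    samples <- stats::approx(seq_len(n), samples, xout = seq_len(n) - lag,
                             rule = 2)$y
  }
  gain * samples
}

# Adds the stochastic part to an already lagged/gained target and
# applies the device model. Uses the current RNG stream.
trial_noise <- function(base, spec, params, trial_index, device) {
  n1 <- spec$n1; n <- spec$n
  e_ran <- trial_error_scale(params$e0_ran, params$einf_ran, params$r_ran,
                             trial_index)
  e_rep <- trial_error_scale(params$e0_rep, params$einf_rep, params$r_rep,
                             trial_index)
  amp <- c(rep(e_ran, n1 + n), rep(e_rep, n))
  total <- n1 + 2L * n
  raw <- base + amp * colored_noise(total, delta_t = device$delta_t) +
    stats::rnorm(total, sd = params$noise_sd)
  quantize_force(raw, device)
}

#' Simulate a participant's full 50-trial session
#'
#' Runs [simulate_trial()] over the whole protocol schedule with
#' per-trial child seeds derived from `seed`, so the session is
#' reproducible and trial traces are mutually independent.
#'
#' @param specs List of five `task_spec`s indexed by task id.
#' @param schedule `protocol_schedule` from [make_schedule()].
#' @param params Participant parameters (see [simulate_trial()]).
#' @param seed Integer seed for this participant.
#' @param participant_id,group Labels carried into scoring output.
#' @param device Device description.
#' @return `participant_trials`: list with `participant_id`, `group`,
#'   `params`, `schedule`, and `measured` (230 x 50 matrix, kg).
#' @export
simulate_participant <- function(specs, schedule, params, seed,
                                 participant_id = "p01", group = "NC",
                                 device = device_model()) {
  stopifnot(length(specs) == 5L, nrow(schedule) == 50L)
  check_participant_params(params)
  sch <- schedule[order(schedule$trial_index), ]
  trial_seeds <- derive_seeds(seed, sprintf("trial%02d", 1:50))
  # lag/gain response to each distinct task, computed once
  bases <- lapply(specs, function(sp) {
    lag_gain_target(sp$samples, params$lag, params$gain)
  })
  measured <- matrix(NA_real_, nrow = 230L, ncol = 50L)
  for (t in 1:50) {
    sp <- specs[[sch$task_id[t]]]
    measured[, t] <- with_seed(trial_seeds[t], {
      trial_noise(bases[[sch$task_id[t]]], sp, params, t, device)
    })
  }
  structure(
    list(participant_id = participant_id, group = group, params = params,
         schedule = sch, measured = measured),
    class = "participant_trials"
  )
}

#' Simulate a cohort of virtual participants
#'
#' Draws `n` participant parameter sets from the preset's population
#' distributions and simulates each full session. With
#' `balanced = TRUE` (default) parameters are drawn by stratified
#' quantiles (one jittered quantile per participant per field, in
#' seed-permuted order), so the cohort's empirical parameter
#' distribution tracks the population marginals; `balanced = FALSE`
#' gives plain iid draws.
#'
#' @param n Cohort size (default sizes: 40 NC, 28 MCI via presets).
#' @param preset `group_preset` ([calibrate_preset()], [nc_preset()],
#'   [mci_preset()]).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param specs List of five `task_spec`s.
#' @param schedule `protocol_schedule`.
#' @param balanced Stratified (`TRUE`) or iid (`FALSE`) parameter draw.
#' @param device Device description.
#' @return `cohort`: list of `participant_trials`, with attributes
#'   `preset_label`, `seed`, `params` (the drawn parameter table).
#' @export
simulate_cohort <- function(n, preset, seed, specs, schedule,
                            balanced = TRUE, device = device_model()) {
  stopifnot(n >= 1L, inherits(preset, "group_preset"))
  seeds <- derive_seeds(seed, c("params", sprintf("participant%03d", 1:n)))
  params <- draw_participant_params(preset, n, seeds[["params"]],
                                    balanced = balanced)
  ids <- sprintf("%s%03d", tolower(preset$label), 1:n)
  cohort <- lapply(1:n, function(i) {
    simulate_participant(specs, schedule, as.list(params[i, ]),
                         seeds[[i + 1L]], participant_id = ids[i],
                         group = preset$label, device = device)
  })
  structure(cohort, class = "cohort", preset_label = preset$label,
            seed = as.integer(seed), params = params)
}
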