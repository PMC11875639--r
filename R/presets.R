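# Group presets and their calibration. A participant's tracking-error
# amplitude in half h decays across trials as
#   e_t = einf + (e0 - einf) * r^(t - 1),
# so the expected block-j mean error has the closed form below and the
# implied learning rate is analytic. Calibration inverts that relation:
# the cohort-level learning-rate distribution is specified directly as
# LR = 100 * (exp(g) - 1), g ~ Normal(mu, sigma) (i.e. 1 + LR/100 is
# log-normal), with (mu, sigma) matched in closed form to a target
# cohort mean and SD; each participant's einf is then solved so that
# the block-10 / block-1 error ratio equals exp(-g) exactly.

#' Expected block-mean error scale under exponential trial-wise decay
#'
#' `e_bar_j = einf + (e0 - einf) * r^(5(j-1)) * (1 + r + r^2 + r^3 + r^4) / 5`,
#' the average of the per-trial scale over the five trials of block `j`.
#'
#' @param e0 Trial-1 error scale (kg).
#' @param einf Asymptotic error scale (kg); may exceed `e0` for a
#'   worsening participant.
#' @param r Per-trial decay multiplier in (0, 1].
#' @param block Block index 1..10 (vectorized).
#' @return Expected block-mean error scale (kg).
#' @export
expected_block_error <- function(e0, einf, r, block) {
  s5 <- (1 + r + r^2 + r^3 + r^4) / 5
  einf + (e0 - einf) * r^(5 * (block - 1)) * s5
}

#' Closed-form learning rate implied by decay parameters
#'
#' `(e_bar_1 - e_bar_10) / e_bar_10 * 100`, in percent.
#'
#' @inheritParams expected_block_error
#' @export
expected_lr <- function(e0, einf, r) {
  b1 <- expected_block_error(e0, einf, r, 1)
  b10 <- expected_block_error(e0, einf, r, 10)
  (b1 - b10) / b10 * 100
}

# Solve einf so that e_bar_10 / e_bar_1 == q given e0 and r.
# Feasible for q in (r^45, q_max) with q_max = (1 - s5 r^45)/(1 - s5).
solve_einf <- function(e0, q, r) {
  s5 <- (1 + r + r^2 + r^3 + r^4) / 5
  r45 <- r^45
  num <- s5 * (q - r45)
  den <- (1 - q) + num
  e0 * num / den
}

# Expected measured block-10 / block-1 AGF ratio under the device noise
# floor sigma0: the per-sample residual at trial t has sd
# sqrt(e_t^2 + sigma0^2), and mean-absolute error is proportional to
# that sd, so the floor inflates blocks with small error scale.
measured_ratio <- function(einf, e0, r, sigma0) {
  e_t <- function(trials) einf + (e0 - einf) * r^(trials - 1)
  b <- function(trials) mean(sqrt(e_t(trials)^2 + sigma0^2))
  b(46:50) / b(1:5)
}

# Realize a target measured block ratio q exactly: solve einf
# numerically against the floor-aware ratio. q is clamped into the
# band reachable with einf in [0, einf_max]; the clamp binds only in
# distribution tails.
solve_einf_measured <- function(e0, q, r, sigma0, einf_max = 50 * e0) {
  q_lo <- measured_ratio(0, e0, r, sigma0)
  q_hi <- measured_ratio(einf_max, e0, r, sigma0)
  q <- min(max(q, q_lo * 1.001), q_hi * 0.999)
  root <- stats::uniroot(function(einf) measured_ratio(einf, e0, r, sigma0) - q,
                         lower = 0, upper = einf_max, tol = 1e-12)
  list(einf = root$root, q = q)
}

#' Calibrate a group preset to target cohort learning rates
#'
#' Chooses the learning-rate population distribution (per half) so that
#' the preset's implied cohort-mean and cohort-SD learning rates equal
#' the targets: with `m = 1 + target/100` and `s = sd/100`,
#' `sigma^2 = log(1 + s^2/m^2)` and `mu = log(m) - sigma^2/2`, so
#' `E[100(e^g - 1)] = target` exactly.
#'
#' @param target_lr_ran,target_lr_rep Target cohort-mean learning rates
#'   (percent, > -100) for the random and repeat halves.
#' @param lr_sd_ran,lr_sd_rep Target cohort SDs of the learning rates
#'   (percentage points).
#' @param label Group label carried through simulation and scoring.
#' @param base Population hyper-parameters for the behavioral fields
#'   ([base_population()]).
#' @return `group_preset` with fields `label`, `fields` (distribution
#'   hyper-parameters), `calibration` (targets and solved values).
#' @export
calibrate_preset <- function(target_lr_ran, target_lr_rep,
                             lr_sd_ran = 35, lr_sd_rep = 35,
                             label = "NC", base = base_population()) {
  if (target_lr_ran <= -100 || target_lr_rep <= -100) {
    stop("target learning rates must exceed -100%")
  }
  stopifnot(lr_sd_ran > 0, lr_sd_rep > 0)
  g_par <- function(target, sd) {
    m <- 1 + target / 100
    s <- sd / 100
    sigma2 <- log(1 + s^2 / m^2)
    c(mean = log(m) - sigma2 / 2, sd = sqrt(sigma2))
  }
  fields <- base
  fields$g_ran <- g_par(target_lr_ran, lr_sd_ran)
  fields$g_rep <- g_par(target_lr_rep, lr_sd_rep)
  structure(
    list(label = label, fields = fields,
         calibration = list(target_lr_ran = target_lr_ran,
                            target_lr_rep = target_lr_rep,
                            lr_sd_ran = lr_sd_ran, lr_sd_rep = lr_sd_rep)),
    class = "group_preset"
  )
}

#' Population hyper-parameters shared by the default presets
#'
#' Log-normal `(meanlog, sdlog)` for: `e0` (trial-1 error scale, kg,
#' median 0.06), `lambda` (per-trial decay rate, `r = exp(-lambda)`,
#' median r 0.93), `lag` (tracking delay in samples, median 0.3),
#' `gain` (response gain, median 1), `noise_sd` (white sensor noise,
#' kg, median 0.003).
#'
#' @return Named list of `(meanlog, sdlog)` pairs.
#' @export
base_population <- function() {
  list(
    e0       = c(meanlog = log(0.06),  sdlog = 0.25),
    lambda   = c(meanlog = log(-log(0.93)), sdlog = 0.35),
    lag      = c(meanlog = log(0.3),   sdlog = 0.5),
    gain     = c(meanlog = 0,          sdlog = 0.005),
    noise_sd = c(meanlog = log(0.003), sdlog = 0.2)
  )
}

#' Default normal-cognition group preset
#'
#' Calibrated to cohort-mean learning rates of 34.6% (random half) and
#' 71.8% (repeat half) with SDs 36.9 / 47.4 percentage points -- the
#' regime in which strong repeat-half learning separates this group
#' from the MCI preset.
#'
#' @return `group_preset`.
#' @export
nc_preset <- function() {
  calibrate_preset(34.6, 71.8, lr_sd_ran = 36.9, lr_sd_rep = 47.4,
                   label = "NC")
}

#' Default mild-cognitive-impairment group preset
#'
#' Calibrated to cohort-mean learning rates of 30.8% (random half) and
#' 28.5% (repeat half) with SDs 32.4 / 32.5 percentage points: random-
#' half learning comparable to the normal-cognition preset, repeat-half
#' learning markedly reduced.
#'
#' @return `group_preset`.
#' @export
mci_preset <- function() {
  calibrate_preset(30.8, 28.5, lr_sd_ran = 32.4, lr_sd_rep = 32.5,
                   label = "MCI")
}

#' Cohort-mean learning rates implied by a preset, in closed form
#'
#' @param preset `group_preset`.
#' @return Named numeric: `lr_ran`, `lr_rep` (percent).
#' @export
preset_expected_lr <- function(preset) {
  stopifnot(inherits(preset, "group_preset"))
  f <- preset$fields
  imp <- function(g) 100 * (exp(g[["mean"]] + g[["sd"]]^2 / 2) - 1)
  c(lr_ran = imp(f$g_ran), lr_rep = imp(f$g_rep))
}

#' Draw iid participant-level learning rates from a preset
#'
#' Samples the preset's learning-rate population distribution directly
#' (no trace simulation): `LR = 100 (e^g - 1)`, `g ~ Normal(mu, sigma)`.
#' Used for distribution-level checks of the statistical machinery.
#'
#' @param preset `group_preset`.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param half `"rep"` or `"ran"`.
#' @return Numeric vector of learning rates (percent).
#' @export
draw_lr <- function(preset, n, seed, half = c("rep", "ran")) {
  stopifnot(inherits(preset, "group_preset"), n >= 1)
  half <- match.arg(half)
  g <- preset$fields[[paste0("g_", half)]]
  with_seed(seed, 100 * expm1(stats::rnorm(n, g[["mean"]], g[["sd"]])))
}

# One stratified or iid standard-normal column per field.
draw_z <- function(n, balanced) {
  if (!balanced) return(stats::rnorm(n))
  u <- (sample.int(n) - stats::runif(n)) / n
  stats::qnorm(u)
}

#' Draw participant parameter sets from a group preset
#'
#' Each behavioral field is drawn from its population distribution;
#' the learning-rate factor `g` is drawn per half and realized exactly
#' by solving the asymptotic error scale `einf` so that the expected
#' *measured* block-10 / block-1 AGF ratio -- including the
#' white-noise and quantization floor, which inflates small error
#' scales -- equals `exp(-g)`, given the drawn `e0` and decay `r`
#' (`r = exp(-lambda)`, clamped to `[0.5, 0.97]` so 50 trials can
#' express the drawn learning rate). With `balanced = TRUE` every
#' field uses jittered stratified quantiles in seed-permuted order.
#'
#' @param preset `group_preset`.
#' @param n Number of participants.
#' @param seed Integer seed.
#' @param balanced Stratified (default) or iid draws.
#' @return data.frame, one row per participant: `lag`, `gain`,
#'   `noise_sd`, and per half `e0_*`, `einf_*`, `r_*`, plus the
#'   realized parameter-level learning rates `lr_ran_true`,
#'   `lr_rep_true` (percent).
#' @export
draw_participant_params <- function(preset, n, seed, balanced = TRUE) {
  stopifnot(inherits(preset, "group_preset"), n >= 1)
  f <- preset$fields
  with_seed(seed, {
    z <- list()
    for (nm in c("e0_ran", "e0_rep", "lam_ran", "lam_rep", "g_ran", "g_rep",
                 "lag", "gain", "noise_sd")) {
      z[[nm]] <- draw_z(n, balanced)
    }
    ln <- function(par, zz) exp(par[["meanlog"]] + par[["sdlog"]] * zz)
    noise_sd <- ln(f$noise_sd, z$noise_sd)
    res <- device_model()$resolution
    sigma0 <- sqrt(noise_sd^2 + res^2 / 12)
    half <- function(suffix) {
      e0 <- ln(f$e0, z[[paste0("e0_", suffix)]])
      r <- exp(-ln(f$lambda, z[[paste0("lam_", suffix)]]))
      r <- pmin(pmax(r, 0.5), 0.97)
      g <- f[[paste0("g_", suffix)]]
      q <- exp(-(g[["mean"]] + g[["sd"]] * z[[paste0("g_", suffix)]]))
      sol <- lapply(seq_len(n), function(i) {
        solve_einf_measured(e0[i], q[i], r[i], sigma0[i])
      })
      list(e0 = e0, einf = vapply(sol, `[[`, numeric(1), "einf"), r = r,
           lr = 100 * (1 / vapply(sol, `[[`, numeric(1), "q") - 1))
    }
    ran <- half("ran")
    rep_ <- half("rep")
    data.frame(
      lag = ln(f$lag, z$lag),
      gain = ln(f$gain, z$gain),
      noise_sd = noise_sd,
      e0_ran = ran$e0, einf_ran = ran$einf, r_ran = ran$r,
      e0_rep = rep_$e0, einf_rep = rep_$einf, r_rep = rep_$r,
      lr_ran_true = ran$lr, lr_rep_true = rep_$lr
    )
  })
}
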