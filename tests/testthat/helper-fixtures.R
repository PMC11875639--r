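# Shared fixtures, built once per test run. Seeds are fixed arbitrary
# constants so every fixture is reproducible.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

fix_lines <- function() memo("lines", function() solve_coefficients(20260922))
fix_specs <- function() memo("specs", function() compose_tasks(fix_lines()))
fix_schedule <- function() memo("schedule", function() make_schedule(104))

# a deterministic, well-behaved participant parameter set
fix_params <- function(lag = 0.3, gain = 1, noise_sd = 0.003,
                       e0 = 0.06, einf = 0.02, r = 0.93) {
  list(lag = lag, gain = gain, noise_sd = noise_sd,
       e0_ran = e0, einf_ran = einf, r_ran = r,
       e0_rep = e0, einf_rep = einf, r_rep = r)
}

# the seeded NC + MCI cohort pair used by the recovery and inference
# checks (shared across test blocks; built on first use)
fix_cohort_pair <- function() {
  memo("cohort_pair", function() {
    seeds <- derive_seeds(20260922, c("nc", "mci"))
    specs <- fix_specs()
    sch <- fix_schedule()
    nc <- simulate_cohort(40, nc_preset(), seeds[["nc"]], specs, sch)
    mci <- simulate_cohort(28, mci_preset(), seeds[["mci"]], specs, sch)
    list(nc = score_cohort(nc, specs), mci = score_cohort(mci, specs))
  })
}

# independent term-by-term Fourier oracle (no vectorized linear algebra)
oracle_line <- function(coefs, phase_s) {
  omega <- task_constants()$omega
  vapply(phase_s, function(t) {
    acc <- coefs$b0
    for (n in 1:6) {
      acc <- acc + coefs$a[n] * sin(n * omega * t) +
        coefs$b[n] * cos(n * omega * t)
    }
    coefs$scale * acc
  }, numeric(1))
}
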