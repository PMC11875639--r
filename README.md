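# gripletrack

Grip-force tracking tasks, motor-learning scores, and synthetic
cohorts for cognitive-decline screening.

## The problem

Mild cognitive impairment (MCI) is marked by early attentional
decline, and motor learning engages attention through two separable
routes: external attention (adjusting movement to sensory feedback)
and internal attention (building and exploiting an internal pattern
representation). A grip-force visual pursuit assessment can separate
the two: a participant squeezes a sprung grip ring (0–0.5 kg range,
1.6×10⁻³ kg resolution, 0.1 s sampling) to keep their force on an
on-screen target line. Each 23 s trial holds 0.25 kg for 3 s, then
shows a 10 s **random** half (one of five different waveforms — an
externally driven adjustment task) and a 10 s **repeat** half
(identical in every trial — an implicit sequence-learning task).
Reduced repeat-half learning with preserved random-half learning is
the MCI signature this package is built to quantify.

gripletrack is for researchers who want to run, simulate, or reanalyze
this assessment: it generates the tasks, scores traces, simulates
calibrated virtual cohorts, and runs the group statistics.

## The model

Target lines are 6-harmonic truncated Fourier series on the
fundamental ω = 2π/18 rad/s,

    f(k) = s · ( b0 + Σₙ₌₁⁶ [ aₙ sin(nω t_k) + bₙ cos(nω t_k) ] ),

solved jointly under start-value (0.25 kg), junction continuity,
junction slope-match, range ([0.06, 0.4] kg), and coefficient-box
constraints. Tracking quality per trial half is the
adjustability-for-grasping (AGF) score, the mean absolute error over
that half's 100 samples:

    AGF = (1/N) Σₖ | f_target(k) − f_measured(k) |     [kg]

Block means average five consecutive trials; the motor learning rate
compares the first and tenth blocks,

    LR = (AGF̄¹ − AGF̄¹⁰) / AGF̄¹⁰ × 100     [%]

computed separately as LR_Ran and LR_Rep. Group comparisons use a
mixed repeated-measures ANOVA on block-wise mean AGF (within: block,
task; between: group) with Mauchly's test and the Greenhouse-Geisser
correction, plus Mann-Whitney (between-group) and Wilcoxon signed-rank
(within-group) tests on the learning rates with bootstrap 95%
intervals — with exact small-sample rank distributions, ties included.

The synthetic-cohort module simulates participants whose band-limited
tracking error decays exponentially across trials through the device's
quantization and clipping; presets are calibrated so a cohort
reproduces target group-mean learning rates (defaults: NC 34.6% /
71.8%, MCI 30.8% / 28.5% for random/repeat, with realistic 30–50
point spreads). See `vignettes/gripletrack-methods.Rmd` for the full
account.

## Worked example

```r
library(gripletrack)

lines    <- solve_coefficients(seed = 42)   # five random lines + repeat line
specs    <- compose_tasks(lines)            # five 230-sample trajectories
validate_task(specs[[1]], others = specs[-1])
#>                           constraint pass    residual tolerance
#> 1                         length_230 TRUE 0.000000000     0e+00
#> 2                      hold_constant TRUE 0.000000000     1e-09
#> 3                 hold_value_0.25_kg TRUE 0.000000000     1e-09
#> 4                  range_0.06_0.4_kg TRUE 0.000000000     1e-09
#> 5                junction_continuity TRUE 0.000000000     1e-09
#> 6               junction_slope_match TRUE 0.002062158     5e-03
#> 7           harmonic_coefficient_box TRUE 0.000000000     1e-09
#> 8 repeat_half_identical_across_tasks TRUE 0.000000000     0e+00
```

Every trajectory holds 0.25 kg for 30 samples, stays in
[0.06, 0.4] kg, ends its random half exactly where the (task-shared)
repeat half begins, and matches slopes across the junction to within
0.005 kg per step.

Simulate and score two calibrated cohorts, then compare them:

```r
schedule <- make_schedule(seed = 7)         # 10 blocks x 5 trials
seeds <- derive_seeds(1, c("nc", "mci", "boot"))
nc  <- score_cohort(simulate_cohort(40, nc_preset(),  seeds[["nc"]],
                                    specs, schedule), specs)
mci <- score_cohort(simulate_cohort(28, mci_preset(), seeds[["mci"]],
                                    specs, schedule), specs)
sprintf("NC : LR_ran %.1f%%  LR_rep %.1f%%",
        mean(nc$lr$lr_ran), mean(nc$lr$lr_rep))
#> [1] "NC : LR_ran 33.8%  LR_rep 71.9%"
sprintf("MCI: LR_ran %.1f%%  LR_rep %.1f%%",
        mean(mci$lr$lr_ran), mean(mci$lr$lr_rep))
#> [1] "MCI: LR_ran 32.8%  LR_rep 30.1%"

compare_between(nc$lr$lr_rep, mci$lr$lr_rep, seed = seeds[["boot"]])
#> mann-whitney (normal approximation): statistic = 874, p = 9.362e-05
#> mean difference = 41.821, 95% CI [22.689, 61.212], n = 40/28
compare_between(nc$lr$lr_ran, mci$lr$lr_ran, seed = seeds[["boot"]])
#> mann-whitney (normal approximation): statistic = 552, p = 0.9255
#> mean difference = 1.001, 95% CI [-15.274, 17.375], n = 40/28
```

The repeat-half learning rate separates the groups decisively while
the random-half rate does not — the dissociation the assessment is
designed around. `run_full_analysis()` bundles the normality screen,
the RM-ANOVA, and all four rank-test comparisons into one
JSON-serializable report, and `run_pipeline(run_config(...))` runs
every stage to files with a checksum manifest. A thin command-line
front end lives at `inst/cli/gripletrack.R`
(`gen-tasks | simulate | score | analyze | run-all`).

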