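---
title: "Methods: task design, AGF scoring, synthetic cohorts, and group statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task design, AGF scoring, synthetic cohorts, and group statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gripletrack)
```

gripletrack implements a device-based motor-learning assessment in
which an older adult tracks an on-screen target force line by
squeezing a sprung grip ring (force range 0–0.5 kg, resolution
1.6×10⁻³ kg, spring constant 4.82×10² N/m, sampled at 0.1 s). The
assessment is built so that tracking error separates two attentional
routes into motor learning: a *random* task half exercising externally
driven motor adjustment, and a *repeat* task half exercising implicit
pattern learning. Reduced repeat-half learning, with preserved
random-half learning, is the signature of interest for mild cognitive
impairment (MCI) screening. This vignette records the models, the
tunable parameters, and the design decisions behind each module.

## Task design

Each 23 s trial is 230 samples $f_d(k)$, $k = 1..230$, at
$\Delta T = 0.1$ s:

$$
f_d(k) =
\begin{cases}
f^i_{\mathrm{Ran}}(N_1) & k = 1,\dots,N_1\\
f^i_{\mathrm{Ran}}(k) & k = N_1+1,\dots,N_1+N\\
f_{\mathrm{Rep}}(k) & k = N_1+N+1,\dots,N_1+2N
\end{cases}
$$

with $N_1 = 30$ preparation samples and $N = 100$ samples per half.
Both line families are 6-harmonic truncated Fourier series on the
fundamental $\omega = 2\pi/18$ rad/s,

$$
f(k) = s\Big(b_0 + \sum_{n=1}^{6} a_n \sin(n\omega t_k) +
  b_n \cos(n\omega t_k)\Big),
$$

where the phase $t_k$ is referenced to the start of the half and
$s = 10^{-2}$ converts display units to kg. Five random lines
($i = 1..5$) and one shared repeat line are solved jointly under:

* start value: every random line equals 0.25 kg at phase 0 (the value
  held through the preparation period);
* continuity: each random line at phase $N\Delta T$ equals the repeat
  line at phase 0;
* slope match: the last backward difference of the random half agrees
  with the first forward step of the repeat half within `slope_tol`
  (default 0.005 kg per sample step — the design only requires
  approximate agreement, so a tolerance has to be chosen; 0.005 kg is
  a quarter of the largest per-sample step the waveforms take);
* range: every sample after the preparation hold lies in
  [0.06, 0.4] kg;
* box: harmonic amplitudes stay within ±5 display units.

`solve_coefficients()` enforces the two equalities exactly by solving
linearly for $b_0$ and $b_1$ of each random line, and satisfies the
remaining constraints by seeded rejection sampling with harmonic
amplitudes drawn from a $3/n$ envelope (smooth lines, high acceptance;
the iteration cap of $10^5$ is never approached in practice). Two
design points deserve a note:

* **The offset $b_0$ is not box-bounded.** Under the fixed $10^{-2}$
  scale the waveform mean must sit near 0.23 kg, i.e. $b_0 \approx
  23$ display units; a $\pm 5$ bound on $b_0$ is incompatible with
  the 0.06–0.4 kg range, so the admissible box applies to the twelve
  harmonic amplitudes only.
* **The preparation hold equals the random line's phase-0 value** and
  that value is pinned to 0.25 kg by the start-value constraint, so
  the first junction is exact by construction.

`validate_task()` is an independent report-only checker used to close
the loop on the solver; `make_schedule()` builds the 10-block × 5-trial
protocol whose first three blocks are the fixed opening
4-3-1-3-4, 1-2-2-4-1, 5-1-5-4-4 with seeded-uniform blocks after, and
a 30 s rest between blocks.

## Scoring

The adjustability-for-grasping (AGF) score of a trial half is the mean
absolute tracking error over that half's 100 samples,

$$
\mathrm{AGF}_{\mathrm{Ran}} = \frac{1}{N}\sum_{k=N_1+1}^{N_1+N}
  \lvert f^i_{\mathrm{Ran}}(k) - f(k)\rvert,
\qquad
\mathrm{AGF}_{\mathrm{Rep}} = \frac{1}{N}\sum_{k=N_1+N+1}^{N_1+2N}
  \lvert f_{\mathrm{Rep}}(k) - f(k)\rvert,
$$

in kg; the 30 preparation samples never enter a score. Block means
average the five trials of each block, and the learning rates compare
first and last blocks:

$$
\mathrm{LR} = \frac{\overline{\mathrm{AGF}}^{1} -
  \overline{\mathrm{AGF}}^{10}}{\overline{\mathrm{AGF}}^{10}}
  \times 100\ [\%],
$$

separately per half. Positive values indicate learning; negative
values (worsening) are admissible. Scores are kept at full precision
internally; the 4-decimal (kg) and 1-decimal (%) rounding applies only
at file export. Missing samples are not imputed — an incomplete trial
or block is an error — and a zero block-10 mean (perfect tracking)
raises an explicit undefined-rate error rather than being clamped,
since clamping would silently bias LR and cannot occur with a noisy
device.

## The synthetic cohort generator

The generator exists so every downstream stage is testable without
the original device or participants. A virtual participant tracks the
target with

* a fractional tracking delay `lag` (samples; linear interpolation,
  median 0.3 ≈ 30 ms),
* a multiplicative response `gain` (median 1, ±0.5%),
* band-limited tracking error: unit-variance Gaussian noise smoothed
  by a Gaussian kernel of width 0.15 s (≈1 Hz bandwidth — human
  corrective movements are band-limited; the true spectrum is not
  identified by block-level data, so this is a stand-in by
  construction), scaled per half by the trial-wise amplitude
  $e_t = e_\infty + (e_0 - e_\infty)\, r^{t-1}$,
* white sensor noise (`noise_sd`, median 0.003 kg),

then passes through the device model: quantization to the
1.6×10⁻³ kg grid and clipping to [0, 0.5] kg. Exponential trial-wise
decay is the simplest monotone learning curve consistent with
block-wise error reduction; the expected block mean has the closed
form

$$
\bar e_j = e_\infty + (e_0 - e_\infty)\, r^{5(j-1)}
  \frac{1 + r + r^2 + r^3 + r^4}{5}.
$$

Worsening participants ($e_\infty > e_0$) are deliberately allowed:
group learning-rate spreads of 30–50 percentage points around means
near 30% imply a sizable minority of negative learning rates, which a
monotone-improvement-only model could not produce.

### Calibration

`calibrate_preset()` specifies the cohort-level learning-rate
distribution directly: $\mathrm{LR} = 100(e^g - 1)$ with
$g \sim N(\mu, \sigma^2)$ per half, and $(\mu, \sigma)$ solved in
closed form so the population mean and SD equal the targets (the
default presets target 34.6%/71.8% with SD 36.9/47.4 for the
normal-cognition group and 30.8%/28.5% with SD 32.4/32.5 for the MCI
group — random-half learning comparable across groups, repeat-half
learning strongly reduced in MCI). Each participant's drawn ratio
$q = e^{-g}$ (block-10 over block-1 error) is then realized *at the
measured level*: the mean absolute error of a trial is proportional to
the residual SD $\sqrt{e_t^2 + \sigma_0^2}$, where
$\sigma_0^2 = \texttt{noise\_sd}^2 + \mathrm{resolution}^2/12$ is the
sensor-plus-quantization floor, so `einf` is solved numerically
against the floor-aware block ratio. Realizing the ratio on the pure
error scale instead would attenuate high learning rates by a few
percentage points, because the floor inflates block-10 AGF more than
block-1 AGF; the floor-aware inversion removes that bias at its source
rather than by post-hoc correction.

### Balanced cohort draws

`simulate_cohort()` draws participant parameters by jittered
stratified quantiles in seed-permuted order (`balanced = TRUE`,
default): each parameter's empirical cohort distribution then tracks
its population marginal, so a single simulated cohort's mean learning
rate estimates the preset target with the residual measurement noise
(≈2–3 percentage points SE at n = 28–40) rather than full
parameter-sampling noise on top. Plain iid draws remain available
(`balanced = FALSE`) and are the right choice when the cohort itself
is the unit of inference — in particular, null-distribution checks of
the between-group test use iid draws from the learning-rate population
(`draw_lr()`), since stratified cohorts would equalize the two groups
by construction and make a rejection-rate check meaningless.

## Statistics

`normality_check()` wraps Shapiro-Wilk screening (report-only; test
selection is configuration-driven). `rm_anova()` fits the mixed design
— within-subject factors block (10) and task half (2), between-subject
factor group — as a multivariate linear model with type-III tests
(via car), reporting Mauchly's sphericity test and both uncorrected
and Greenhouse-Geisser-corrected p-values for every within effect;
the corrected value is the headline. One property worth stating
explicitly: the correction rescales both degrees of freedom by
$\hat\varepsilon \le 1$, which enlarges the p-value whenever
$F \gtrsim 1$ but can *shrink* it for $F < 1$; a blanket
"corrected ≥ uncorrected" rule does not hold for the standard
correction, and this package reports the standard quantities rather
than clamping them.

The learning-rate comparisons use rank tests with exact small-sample
distributions computed on tie-adjusted (average) ranks: the
Mann-Whitney test enumerates all group assignments when
$\binom{n+m}{n} \le 2\times10^5$, and the Wilcoxon signed-rank test
builds the exact null of the tied-rank statistic by
generating-function convolution for up to 25 non-zero differences.
Larger samples use the normal approximation with tie and continuity
corrections. All tests are two-sided at α = 0.05 with no
multiple-testing adjustment (none is part of the analysis plan).
Interval estimates are seeded bootstrap percentile intervals
(10⁴ resamples by default) for the difference in group means
(between) or the paired mean difference (within); a bootstrap
interval was chosen because the analysis plan calls for a 95%
interval on the mean difference without committing to a
normal-theory, rank-based, or Bayesian construction.

## Numerical and reproducibility choices

* All randomness flows from one master seed through named child
  streams (`derive_seeds()`); identical configurations reproduce
  byte-identical outputs, and `run_pipeline()` writes a manifest with
  child seeds and artifact checksums.
* Sample indexing is 1-based ($k = 1..230$) and file exports carry
  $t = (k-1)\Delta T$ seconds.
* Degenerate inputs fail loudly: constant data in the normality
  screen, all-zero differences in the signed-rank test, unbalanced
  ANOVA cells, partial blocks, zero block-10 means.
* An all-constant ANOVA table short-circuits to a "no effect" report
  (the multivariate fit would be singular).
* Clipping is applied before quantization, so every emitted force is
  representable on the device grid and inside [0, 0.5] kg.

## What the tests do and do not show

The test suite verifies the pipeline against brute-force oracles
(term-by-term Fourier sums, loop-computed AGF, enumerated rank
distributions), checks solver constraints exactly, recovers the four
preset learning-rate targets from full simulated cohorts (n = 40 and
28, within ±5 percentage points), reproduces the qualitative group
structure (repeat-half separation at p < 0.01, no random-half
separation, within-group repeat > random in the normal-cognition
group), holds the 5% size of the between-group test over 500 null
replicates, and detects the block × task × group interaction in the
majority of 100 replicate cohort pairs. Monte-Carlo checks use those
problem sizes to keep a full run in a few minutes.

Passing these tests shows the *machinery* is correct and the
generative model is calibrated to the target group structure. It does
not show that real participants behave like the generative model: the
within-trial error spectrum, the trial-wise decay law, the
independence of the two halves' learning factors within a
participant, and the absence of fatigue, attention lapses, or trial
exclusions are all modeling conveniences chosen for transparency, not
properties inferred from data. Conclusions about real cohorts require
real traces scored through the same `score_cohort()` path.
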