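---
title: "Models and methods behind vwtsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vwtsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vwtsim)
```

`vwtsim` simulates the visual water task — a two-alternative forced-choice
(2AFC) swim task in which mice discriminate gratings — and implements the
analysis chain used to turn trial logs into contrast-sensitivity (CS) and
visual-acuity (VA) thresholds, learning statistics, and intrinsic-signal
imaging readouts. This vignette records the models, the reasoning behind
every tunable default, and the numerical decisions, so that users know
exactly what passing tests do and do not establish.

## The observer model

### Psychometric function

Performance is modeled as
$$p(x) = \gamma + (1 - \gamma - \lambda)\, F(\log_{10} x;\ \alpha, \beta),$$
with $F$ a logistic oriented so performance rises for easier stimuli
(higher contrast; lower spatial frequency). Parameters:

* $\gamma = 0.5$ — the 2AFC guess rate; fixed by the task, not tunable.
* $\lambda$ (lapse rate, default 0.02) — stimulus-independent errors. The
  behavioral protocol expects mice to reach "near-perfect" (90% or better)
  performance on easy stimuli during shaping, so $\lambda$ must be well
  below 0.1; 0.02 puts the easy-stimulus ceiling at 98%.
* $\alpha$ — the threshold, in the stimulus' own units (Michelson contrast
  in $(0,1]$, or cpd). The logistic offset is chosen so that
  $p(\alpha) = 0.70$ *exactly*, whatever $\lambda$: the assessment
  procedure defines threshold as the 70%-correct level, and parameterizing
  $\alpha$ at that criterion (rather than at the 50% point of $F$) makes
  printed group thresholds map one-to-one onto model parameters.
* $\beta$ — slope per log10 unit. Defaults: 8 in the contrast domain, 25 in
  the SF domain. The SF value is larger because the acuity range of the
  mouse (roughly 0.3–0.8 cpd) spans only ~0.4 log10 units, and the 0.03 cpd
  assessment step must produce a measurable performance drop (about 8
  percentage points one step past threshold) for the staircase to converge;
  the contrast slope produces a comparable drop per 0.1 contrast step near
  naive thresholds.

### Learning dynamics

Perceptual learning is a saturating exponential in "effective dose":
$$\alpha(d) = \alpha_\infty + (\alpha_0 - \alpha_\infty)\, e^{-d/\tau},$$
where $d$ counts scored (non-correction) trials lying within
`proximity_bandwidth` log10 units of the *current* threshold. This encodes
the core empirical asymmetry of near-threshold training: easy-stimulus
control training (100% contrast or 0.12 cpd, >0.5 log10 units from any
calibrated threshold) accumulates no dose and therefore drives no learning.
No mechanistic cortical model is implied; the functional form is the
simplest monotone saturating curve consistent with gradually rising daily
values over 35 days.

Defaults and why:

* `proximity_bandwidth` — 0.25 (contrast) / 0.15 (SF) log10 units. The
  window must contain the one-step tracking range of the training
  staircase, since training deliberately hovers within a step of threshold:
  a 0.1 contrast step near a threshold of 0.14–0.27 spans 0.17–0.23 log10
  units, while the 0.03 cpd acuity step spans under 0.03. Control levels
  stay far outside both windows.
* `tau` — 150 effective trials. Under the default two sessions × 10 scored
  trials per day, roughly half the scored trials fall inside the window
  (the tracker oscillates a step either side of threshold), giving ~11
  effective trials/day and a day-35 dose near 380: the threshold closes
  >90% of its gap to the asymptote by the end of training, while at day 18
  a substantial residual remains — preserving the empirical ordering that
  four daily sessions outperform two at day 18.
* `interocular_transfer_fraction` — 0.63. Monocular training shifts the
  untrained eye's log threshold by this fraction of the trained eye's
  shift, the value implied by the published 67% (trained) vs 42%
  (untrained) improvements on the log scale.
* `task_transfer` — pattern-discrimination training carries 0.90 of its
  improvement into detection; detection training carries only 0.07 into
  discrimination. These encode the published asymmetric transfer-index
  values as generator inputs; the package makes no mechanistic claim about
  why the asymmetry exists. Orientation is not a learning dimension
  (transfer across orientations is essentially complete), so thresholds are
  orientation-independent.
* Between-animal variability — log-normal $\alpha$ with SD 0.05 log10
  units. Published SEMs at the published group sizes imply a total
  coefficient of variation near 0.14 (≈0.06 log10 units); since measured
  spread includes staircase estimation noise on top of true between-animal
  spread, the generator's true-threshold SD is set slightly below that
  arithmetic value.
* Retention — after training stops, $\alpha$ relaxes toward baseline
  exponentially with a 64-day half-life, the single value consistent with
  both published retest retention coefficients (74% at 28 days, ~63% at 45
  days). Group retention inputs are not printed per animal, so this is a
  consistency calibration, not a fitted quantity.

The `old` profile is an explicit placeholder: no numerical baseline exists
for aged animals, so its threshold (0.40 cpd) and slowed learning
(`tau` = 450) are configurable stand-ins, flagged `calibrated = FALSE`.

### Randomness

One master seed governs a cohort; each animal derives a child stream via a
stable integer hash of (seed, id), so cohorts are bit-reproducible and
independent of evaluation order. A second-level child seed separates the
threshold draw from the trial-level assessment stream.

## The assessment procedure

The staircase starts at the easiest level (contrast 1.0, or 0.12 cpd) and
moves one step harder after each passed criterion block (pass: 4
consecutive correct, or 7 correct within a 10-trial block, evaluated
sequentially with early stopping; fail: block completes without either). A
failed level is recorded as a preliminary threshold and the staircase
reverses one step easier. The run ends when two successive preliminary
thresholds agree within one step — our operationalization of "repeat until
performance is stable", which the protocol leaves qualitative — and the
final estimate is read from the frequency-of-seeing (FOS) curve over all
pooled scored trials: the crossing of 70% accuracy nearest the easy end,
linearly interpolated between tested levels.

Numerical and edge-case decisions:

* **Correction trials** (forced repeats after an error) are logged but
  excluded from criterion tests and FOS accuracy by default: they follow a
  predictable error and would bias accuracy. `include_corrections = TRUE`
  restores them for sensitivity analyses.
* **Blocks** are fixed 10-trial windows, not sliding.
* **Linear interpolation on raw points** implements "where the curve
  intersects 70%" with no auxiliary fit; an isotonic-regression mode
  (`mode = "isotonic"`) is available when sampling noise makes the curve
  non-monotone. With multiple crossings, the raw mode uses the crossing
  nearest the easy end.
* **Degenerate observers**: at-chance performance at the easiest level
  yields a `defined = FALSE` estimate ("below criterion at easiest tested
  level"), never an error; an observer above criterion everywhere yields
  "floor not reached". Contrast cannot descend below one step (0.10), and
  a safety cap of 200 blocks guarantees termination.
* **Session bookkeeping**: 10 scored trials per session, two sessions per
  day by default (configurable to four), matching the behavioral schedule.
* The ascending-VA staircase uses the same 0.03 cpd step in both
  directions; the protocol states only the increment, and symmetry is
  assumed.

The estimator carries a small upward bias (under +0.02 cpd at the lowest
acuities; well within one step in both domains, verified over α grids):
blocks that end at an early-stopped pass record upward-biased accuracy at
that level. This is a property of the published procedure itself, which the
package reproduces deliberately rather than corrects.

## Training simulation

Each training day runs the configured sessions as criterion blocks at the
current level; pass moves one step harder, fail one step easier (the same
step sizes as assessment — the protocol says only "in steps"). The daily
trajectory value is the threshold re-estimated from that day's own FOS
curve; when a day's 20–40 trials produce no criterion crossing (routine for
control animals that never fail at 100% contrast), the last defined value is
carried forward from the pre-training assessment. The post-training value is
the arithmetic mean of the final four daily values, exactly.

Because a day contributes only ~20 scored trials at one or two levels, daily
values are noisy and the coarse contrast grid (0.2/0.1 near trained
thresholds) interpolates a few percent below the latent CS; the group-mean
trajectory rises monotonically toward, but measured slightly under, the
calibrated asymptote. Tests therefore check the latent threshold's
convergence and the measured trajectory's direction separately.

## Learning metrics

All formula-defined statistics are implemented directly: percent improvement
$(\mathrm{post}-\mathrm{pre})/\mathrm{pre} \times 100$, post/pre ratio
(PPR), retention coefficient
$(\mathrm{retest}-\mathrm{pre})/(\mathrm{post}-\mathrm{pre}) \times 100$,
transfer index
$(\mathrm{post}-\mathrm{naive})_{untrained}/(\mathrm{post}-\mathrm{pre})_{trained}$,
sucrose preference, and spine density per 10 µm (rejecting segments under
25 µm). Group improvement figures are computed per animal and then averaged
(`group_prepost(..., "per_animal")`, the default), because published group
percentages are means of per-animal statistics, which differ from statistics
of group means; a `group_means` mode exists, and the transfer index is
necessarily computed on group means since the untrained comparison is a
different (naive) cohort. SEM uses the sample SD; for n = 1 the SEM is
reported as 0 and flagged. Reporting precision follows the field: two
decimals for TI and PPR, whole percent for improvements.

## Imaging

The synthetic cortex embeds, in a Gaussian responsive region, either a
0.1 Hz sinusoidal reflectance modulation whose phase ramps across one axis
(periodic retinotopy mode) or an episodic reflectance *decrease* per
grating trial whose amplitude falls linearly with SF to zero at the true
cut-off (0.39 cpd trained / 0.27 cpd untrained profiles), plus white noise
and a slow uniform drift. The default fractional response amplitude
(2×10⁻³) and noise (5×10⁻⁴ per pixel-frame) are typical intrinsic-signal
magnitudes: signals of order 0.1% of baseline reflectance, far below
single-frame noise, recoverable only by trial averaging — which is exactly
what the analysis must demonstrate.

Analysis decisions:

* **Frame rate** 5 frames/s (the acquisition rate is not part of the
  published record); all windows are specified in seconds and converted by
  rounding to the nearest frame.
* **Fourier retinotopy** truncates to a whole number of stimulus cycles so
  a constant stack yields exactly zero magnitude, and scales so a pure
  cosine of amplitude A returns A. Opposite sweep directions are combined
  by phase averaging, which cancels the common hemodynamic delay.
* **ΔR/R maps**: per trial, the mean frame over the 2–6 s post-onset
  window minus the 1 s pre-stimulus blank, divided by the blank; trial maps
  averaged over 32 trials. Maps are stored signed (responses negative);
  tuning curves report positive response magnitude. A zero blank pixel is
  an error, not an Inf.
* **Smoothing**: circular averaging disk of radius 3 px (51 µm at
  17 µm/px), with renormalized partial disks at borders — no padding
  artifacts, constant maps are exactly invariant.
* **ROI**: top decile of the lowest-SF condition's smoothed response
  magnitude, emulating a hand-drawn binocular-V1 region.
* **Cut-off fit**: ordinary least squares through the ROI tuning points
  with response above a noise floor (2× blank SD, shrunk by the
  trial-and-ROI averaging factor) plus the first subthreshold condition,
  i.e. a zero-crossing extrapolation; a full-range fit is available. The
  fit requires a genuinely negative slope (flat tuning is rejected with an
  explicit error, using a scale-relative epsilon) and warns when the
  crossing extrapolates far beyond the tested range. Because the first
  subthreshold condition is clipped to zero rather than negative, the
  noiseless recovery is biased high by ~0.005–0.015 cpd (0.394 for truth
  0.39; 0.284 for truth 0.27) — a property of zero-crossing extrapolation
  on rectified tuning, accepted as within half a condition step.
* **Phase scatter** (map quality): mean absolute circular deviation of
  each suprathreshold pixel's phase from the local disk circular mean.
  Smooth gradients score near zero; uniform-random phases approach the
  circular-uniform expectation (π/2).

## What the generator does and does not emulate

The synthetic observer reproduces: Bernoulli trial outcomes with the
correct psychometric structure, criterion-test and staircase dynamics,
between-animal threshold spread, saturating near-threshold learning with
control-condition inefficacy, interocular and asymmetric task transfer, and
retention decay. It does **not** model swim kinematics, latency,
motivation, thigmotaxis, body weight, or any physiological stress variable;
the sucrose-preference and spine-density operations are pure formula
implementations for analyzing externally supplied measurements. The
synthetic cortex reproduces the linear SF-response decline, retinotopic
phase gradients, hemodynamic timing, noise, and drift, but not vascular
artifacts, motion, or anesthesia-state changes — so passing tests validate
the *estimators* under their stated assumptions, not the biology.

Simulated cohort sizes in the tests and the acceptance script match the
published group sizes (21 contrast-assessed naive animals, 42 SF-assessed,
15 amblyopic, 10 imaged animals); imaging stacks default to 64×64 px with
32 trials per condition, and tests use smaller geometries where only
algebraic properties are at stake.

## Known limitations

* Inferential statistics (ANOVA families, post hoc tests) are deliberately
  out of scope; the package emits tidy per-animal tables for any stats
  package.
* Group improvement percentages computed over unprinted per-animal values
  cannot be reproduced numerically, only directionally.
* The amblyopic fellow eye and the `old` profile have partially or wholly
  unconstrained parameters, documented above.
* The daily trajectory estimator is intentionally faithful to a
  low-trial-count daily readout and therefore noisy; users wanting precise
  daily thresholds should lengthen sessions rather than expect the
  estimator to denoise.
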