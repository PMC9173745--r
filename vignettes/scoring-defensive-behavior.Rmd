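---
title: "Scoring freezing, darting, and flight from locomotion traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring freezing, darting, and flight from locomotion traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darter)
```

## The measurement problem

In rodent Pavlovian fear conditioning, the conditional response that is
almost universally measured is freezing: complete immobility except for
respiration. Under some training procedures — notably a serial compound in
which a 10 s tone is followed by a 10 s white noise ending in a 1 s
footshock — the noise instead elicits bursts of locomotion, jumping, and
brief ballistic "darts". If only freezing is scored, that behavior is
invisible; if flight is scored naively, slow repositioning movements are
conflated with genuine high-velocity bursts. `darter` implements the three
complementary measures this literature uses, their trial bookkeeping, and
the inferential layer on top, plus a synthetic session generator with known
ground truth so the whole pipeline can be validated by parameter recovery.

The three measures, each computed per trial period:

* **Percent freezing.** The per-frame activity signal (pixel change between
  adjacent video frames, nominally 30 frames/s) is thresholded; a maximal
  run of sub-threshold frames lasting at least 1 s is a freezing bout, and
  percent freezing over a period is the fraction of that period covered by
  bouts. The activity threshold itself is rig-specific (calibrated against
  hand scoring) and is therefore a parameter, not a constant.
* **Peak activity ratio (PAR).** For a window of interest (e.g. the 10 s of
  a CS), `PAR = During / (During + PreStim)` where `During` is the largest
  activity sample in the window and `PreStim` the largest in the
  equal-duration window immediately preceding the stimulus onset. 0.5 means
  nothing during the CS exceeded pre-CS behavior; values near 1 mean a
  burst far above baseline. PAR captures the *amplitude* of the largest
  movement.
* **Darts.** From the velocity trace (center-point tracking, nominally
  3.75 Hz), darts are local maxima at or above a threshold velocity
  (default 22.9 cm/s) separated by at least 0.8 s. Dart counts and rates
  capture the *frequency* of discrete ballistic movements, and dart
  magnitudes and latencies their topography.

## Conventions that make the scores well defined

Published descriptions of these measures leave several numerical details
open. The package pins them down explicitly; each is a documented,
test-covered choice.

**Time.** Everything is in seconds from session start. Sample `i` (1-based)
of a trace with rate `r` and origin `t0` sits at `t0 + (i - 1)/r`. All
windows are half-open `[start, end)`, so contiguous periods never
double-count a sample and freezing time is additive across a partition of a
period.

**Freezing bouts.** Sub-threshold is *strictly* below the threshold, and
bout boundaries snap to frame times: a run of `k` sub-threshold frames is a
bout of `k/r` seconds, with a run of exactly `min_bout * r` frames
included. Whether the original scoring software rounds bout durations by
frame count or wall clock is not documented anywhere we know of; the
frame-count rule is the one that makes bouts exactly reproducible from the
exported signal. A bout spanning a period boundary is clipped, not
reassigned, which conserves total freezing time.

**Dart candidates.** A dart is a *local maximum* at or above threshold, not
a mere threshold crossing — one event per velocity surge, which is what the
"minimum interpeak interval" language implies. Plateaus of equal values
count once, at their first sample. Among candidates closer than the minimum
interval, suppression is greedy in descending magnitude with ties going to
the earlier peak: this preserves the largest peaks, and therefore the
magnitude statistics that downstream analyses compare. Both the local-max
rule and the keep-the-larger rule are configurable conventions rather than
published facts; the detector is property-tested against an independent
brute-force implementation of the same stated rule.

**Threshold derivation.** The canonical 22.9 cm/s threshold is defined as
the 99.5th percentile of pooled baseline velocity collected before any
stimulus or shock. The empirical percentile uses linear interpolation
between order statistics (R's default `quantile` type 7); with fewer than
200 pooled samples the function refuses and points the user at the fixed
default, since an extreme percentile of a tiny pool is meaningless.

**PAR windows.** PreStim is the equal-duration window immediately before
the stimulus onset. For the second component of a serial compound this is
the preceding component's window (the literal reading of "immediately
preceding"); for a shock period, which is much shorter than a CS, the
equal-duration window before the trial's first CS onset is used. The
degenerate 0/0 case (no movement in either window) returns 0.5 — no
movement exceeded baseline — keeping the interpretation of 0.5 continuous.

**Early vs late darts.** Darts in the first 3 s of a 10 s CS are "early"
(onset-locked, startle-like); the boundary is half-open, so a latency of
exactly 3.000 s is late.

**Shock reactivity** is the peak velocity from shock onset to 1 s past
shock offset; bursts reliably outlast a 1 s shock, and a stated window is a
testable one.

**Binned traces.** Averaged velocity traces use bins of 2 samples
(0.533 s at 3.75 Hz); a trailing partial bin is dropped rather than padded,
avoiding bins with inflated variance. Averaging order is trials within
subject, then subjects within group — this matters for error bars and is
fixed. Bin alignment is a parameter (`align_to`), defaulting to the period
start.

**Within-subject error bars.** Group traces report the subject-mean
normalization SE: each subject's bin vector is recentred to the grand mean,
the per-bin SD of recentred values is inflated by `sqrt(C/(C-1))` (`C` =
number of bins) to undo the variance the recentring removes, and divided by
`sqrt(n)`. Subjects who differ only by an overall offset contribute zero
SE, which is the point of a repeated-measures error bar.

## The inferential layer

`rm_anova()` implements the univariate repeated-measures / split-plot
ANOVA (subjects nested in between-group cells, within factors crossed
within subject) on the per-(subject, trial, period) metric tables. The
published analyses this mirrors report integer or epsilon-scaled degrees of
freedom of exactly this design, which is why it is a split-plot ANOVA and
not a multilevel regression. Mauchly's test gates the Greenhouse-Geisser
correction: when sphericity is rejected (p < 0.05 by default), both degrees
of freedom are multiplied by the GG epsilon and the p-value recomputed; a
2-level within factor is trivially spherical. Sums of squares are Type III
by default for unbalanced between factors (configurable). The machinery
underneath is `car::Anova` on a multivariate linear model — the standard R
backbone for this analysis — while the package's tests check the F values
against an explicit sums-of-squares decomposition coded independently.

`welch_anova()` (heteroscedastic one-way ANOVA with Welch-Satterthwaite
fractional denominator df) is used for dart-magnitude comparisons where
variances differ strongly across stimulus types; `paired_t()` handles
within-subject magnitude contrasts (first vs second dart of a multi-dart);
`posthoc_pairwise()` provides Bonferroni-adjusted pairwise t-tests
(`p_adj = min(1, m p)`) and Tukey studentized-range comparisons. All tests
are two-sided.

One caveat the tests make explicit: the common claim that the GG-corrected
p-value is never smaller than the uncorrected one holds in the rejection
region (F of at least about 1). For F well below 1 shrinking both degrees
of freedom can lower the (large) p-value; the correction is only ever
interesting where F is large, so the conservatism property is tested there.

## The synthetic session generator

`simulate_session()` is a first-class, tested component, not a fixture. It
emulates the statistical structure of sessions in this paradigm:

* **Baseline locomotion** is a stationary lognormal AR(1) speed process:
  `baseline_mean_speed` is the median (default 4 cm/s),
  `baseline_sd` the approximate marginal SD (default 3.05 cm/s, moment
  matched on the log scale), and `baseline_ar_coeff` the log-scale
  autocorrelation (default 0.6). The defaults place the 99.5th percentile
  of pooled baseline speed near 22.9 cm/s, so the canonical threshold is
  self-consistent with the synthetic baseline. No published speed
  distribution exists for these chambers; this is a convenience
  calibration, and the generator makes no claim of kinematic realism.
* **Freezing** is generated in slots aligned to the velocity sample grid
  (4 samples = 1.067 s at 3.75 Hz, so bout edges land exactly on both the
  velocity and the frame grid): within a CS the freezing
  probability follows associative fear (`pairings x assoc_increment`,
  plus half the context fear); outside stimuli it follows context fear,
  which grows by `context_fear_increment` per shock. Adjacent freezing
  slots merge into bouts, during which speed is forced below
  `freeze_speed_ceiling` (1 cm/s) and activity below 80% of the freezing
  threshold.
* **Darts** are single-sample velocity transients (3.75 Hz cannot resolve
  sub-270 ms kinematics, so one sample *is* the detector's operating
  resolution). Each tone/noise onset emits a dart with probability
  `clamp(sensitization_gain x n_shocks) x habituation_decay^n_exposures`,
  using the running shock and exposure counts at that moment — so darting
  emerges over training day 1 and habituates within a session. Subjects
  with prior pairings of a CS additionally emit a slower mid-CS dart with
  probability `late_dart_prob_paired`, reproducing the late activity peak
  characteristic of paired groups. Dart peaks are truncated normal
  (onset mean 35 cm/s; late darts at 75% of that), bounded below by the
  freeze ceiling so every ground-truth dart is detectable in principle.
* **Shocks** always emit a reactivity burst (mean peak 60 cm/s with a
  2-sample decaying tail), always the largest movements in a session.
* **Activity** is a monotone noisy transform of speed (default 20 activity
  units per cm/s with 10% lognormal frame noise, 8 frames per velocity
  sample), so freezing (activity-based) and darting (velocity-based)
  scoring operate on consistent signals even though real rigs derive them
  from different software streams.

The learning state (`subject_state()`) is a small deterministic automaton —
shock count, per-stimulus exposure counts, per-CS pairing counts, scalar
context fear — updated by each session's events. Because the update does
not depend on the realized noise, multi-day designs can advance the state
without synthesizing the intervening days (`advance_state()`), which keeps
test-day-only studies cheap.

All randomness in a session is drawn in a schedule-determined order
(baseline innovations, then per-event uniforms, then freezing slots, then
activity noise), with truncated-normal magnitudes drawn by quantile
transform rather than rejection. Two consequences: a given
`(schedule, params, state, seed)` is bit-reproducible, and raising a
probability parameter under a shared seed changes event indicators
monotonically — the monotone-sensitization property of the generator holds
pathwise, not just in expectation.

**Calibration of the defaults.** Where the source literature fixes a value
(trial counts, stimulus durations, ITI range 150-210 s, 1 s shock, n = 8
per group) the defaults are that value. Where it does not, defaults were
chosen once, during model design, to realize the qualitative structure the
paradigm reports: ten pairings produce strong but non-saturating CS
freezing (`assoc_increment` 0.06, `fear_freeze_slope` 0.9), shock history
alone makes a novel noise elicit onset darts in most trials
(`sensitization_gain` 0.08 with 10 shocks), ten prior exposures cut the
onset-dart probability to about a fifth (`habituation_decay` 0.85), and
paired subjects gain a mid-CS dart (`late_dart_prob_paired` 0.4). Under
these defaults the simulated pseudoconditioning experiment reproduces the
qualitative test-day ordering — PAR to a novel noise: shock-only > paired >
no-shock, freezing greatest in the paired group — which the acceptance
suite checks across 20 seeded cohorts.

**What passing tests do and do not show.** The generator produces
uncorrelated lognormal baselines, slot-aligned freezing, and
single-sample darts. Real data have slow drifts, grooming and rearing
artifacts, tracking dropouts, and movements of intermediate speed; recovery
of ground truth here validates the *scoring logic* (thresholding, run
lengths, peak suppression, window bookkeeping), not robustness to every
artifact of real video tracking. The false-positive dart rate on real data,
for instance, is governed by the baseline's upper tail, which is exactly
what the 99.5th-percentile threshold convention controls — by construction
about 0.5% of genuine baseline samples exceed it, and the synthetic
baseline reproduces that, so occasional "baseline darts" in simulated
output are a feature of the convention, not a bug of the detector.

## Problem sizes used in the validation suite

The test suite chooses sizes that exercise each property cleanly: detector
equivalence with the brute-force oracle is exhaustive over all velocity
traces up to length 8 on a 3-letter alphabet and randomized up to length
50; dart recovery runs 500 simulated two-trial sessions under separated
scales (clamped baseline below half the threshold, dart peaks above twice
the threshold); freezing recovery runs 100 sessions at 2-percentage-point
tolerance; the null calibration of the ANOVAs runs 1000 replicates of a
12-subject, 2-trial design and requires empirical type-I error within
[0.03, 0.07] at alpha 0.05; the pseudoconditioning ordering uses 20 cohorts
of 8 at the full 16-trial test-day design. The in-silico experiments use
the same trial structures as the corresponding animal designs.

## A worked example

```{r example, eval = FALSE}
library(darter)

params <- behavior_params()

# Pseudoconditioning: shocks only in training, novel noise at test
cohort <- simulate_cohort(2, "shock_only_noise_test", n_per_group = 8,
                          params = params, seed = 1)
scored <- score_cohort(cohort, group = "shock_only",
                       freeze_threshold = params$activity_freeze_threshold)

# test-day noise-period metrics
noise <- subset(scored$metrics, phase == "test" & period == "noise")
aggregate(cbind(percent_freezing, par, darts_per_min) ~ subject_id,
          noise, mean)

# dart magnitude by period, Welch ANOVA
darts <- subset(scored$darts, period_kind %in% c("noise", "shock"))
welch_anova(split(darts$magnitude, darts$period_kind))
```

## Known limitations

* The generator models neither spatial position (thigmotaxis, dart
  direction) nor estrous/sex structure; sex enters analyses only as a
  factor column the user provides.
* Freezing is slot-aligned at 1 s resolution, so synthetic bouts are
  integer-second; the scorer itself resolves bouts at frame resolution.
* `rm_anova()` requires complete within-subject data (no imputation of
  missing cells), and its constant-response convention (F = 0) is a
  pragmatic boundary case, not a statistical statement.
* Readers of tracking-software exports target the package's documented
  text layout; adapting vendor spreadsheets to it is a one-off reshaping
  step outside the package.
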