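# darter

Quantifying defensive behavior — freezing, darting, and flight — from
rodent locomotion time series in Pavlovian fear-conditioning experiments.

## The problem

Fear-conditioned rodents do not only freeze. Under some procedures
(notably a serial compound CS: 10 s tone, then 10 s white noise, then a
1 s footshock) the noise elicits bursts of locomotion and brief ballistic
"darts" instead. Scoring that behavior reproducibly requires pinned-down
conventions for three measures computed from video-tracking exports, per
trial period:

* **Percent freezing** — maximal runs of per-frame activity strictly below
  a threshold, lasting ≥ 1 s, as a fraction of each analysis period.
* **Peak activity ratio (PAR)** — `During / (During + PreStim)` of the
  window-peak activity, where PreStim is the equal-duration window
  immediately before stimulus onset. 0.5 = nothing exceeded baseline;
  → 1 = a burst far above it.
* **Darts** — velocity peaks ≥ 22.9 cm/s (the 99.5th percentile of pooled
  baseline speed, recomputable with `derive_dart_threshold()`) with a
  minimum 0.8 s inter-peak interval, counted, rated per minute, and
  classified by latency (early = first 3 s of the CS) and magnitude.

`darter` implements these measures, the trial designs of the standard
pseudoconditioning/habituation control experiments, binned group-average
velocity traces with within-subject-corrected error bars (subject-mean
normalization with the C/(C−1) variance correction), and the matching
inferential layer: repeated-measures/split-plot ANOVA with Mauchly-gated
Greenhouse–Geisser correction, Welch's heteroscedastic ANOVA, paired t,
and Bonferroni/Tukey post hocs. A synthetic session generator with ground
truth (`simulate_session()`, `simulate_cohort()`) makes the whole pipeline
testable by parameter recovery; see the vignette
`vignettes/scoring-defensive-behavior.Rmd` for the model and every
numerical convention.

## Worked example

Simulate a pseudoconditioned cohort (2 days of shocks only, then a novel
10 s noise at test), score it, and compare dart magnitudes across periods:

```r
library(darter)
params <- behavior_params()
cohort <- simulate_cohort(2, "shock_only_noise_test", n_per_group = 8,
                          params = params, seed = 1)
scored <- score_cohort(cohort, group = "shock_only",
                       freeze_threshold = params$activity_freeze_threshold)

noise <- subset(scored$metrics, phase == "test" & period == "noise")
round(colMeans(noise[c("percent_freezing", "par", "darts_per_min")]), 3)
#> percent_freezing              par    darts_per_min
#>           27.014            0.587            2.344

darts <- subset(scored$darts, period_kind %in% c("noise", "shock"))
welch_anova(split(darts$magnitude, darts$period_kind))
#> group: W[1, 126.93]=467, p=2.325e-44
```

Read: at test the previously-shocked animals freeze moderately to the
novel noise, their PAR of 0.59 means peak activity during the noise
clearly exceeded the pre-noise baseline, and they dart about 2.3
times/min during the 10 s CS. The Welch test compares the 50
noise-elicited dart magnitudes against the 80 shock-period burst
magnitudes from the synthesized training days: reactivity to shock is far
larger than darting to the noise.

Single-session scoring of real exports works the same way:
`read_trace()` + `read_schedule()` + `score_session()`. A thin CLI over
the same functions is in `inst/scripts/darter-cli.R` (subcommands
`simulate` and `score`).

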