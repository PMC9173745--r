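Package: darter
Title: Scoring Freezing, Darting, and Flight from Rodent Locomotion Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying defensive behavior in rodent fear
    conditioning experiments from video-tracking exports. Scores freezing as
    sub-threshold activity sustained for at least one second, quantifies
    flight with the peak activity ratio (PAR) and with dart detection from
    velocity traces (supra-threshold local maxima with an enforced minimum
    inter-peak interval), segments sessions into trial periods, bins velocity
    traces with within-subject-corrected error bars, and provides the
    matching inferential layer (repeated-measures ANOVA with
    Greenhouse-Geisser correction, Welch's ANOVA, paired t-tests, and
    Bonferroni or Tukey post hoc comparisons). Includes a synthetic session
    generator with ground-truth freezing bouts, darts, and shock-reactivity
    bursts under standard Pavlovian trial designs, so the full scoring
    pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
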