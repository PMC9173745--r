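#' Trial designs of the four fear-conditioning experiments
#'
#' Builds the per-day event schedules for one group of one of the four
#' experimental designs: serial-compound replication and its stimulus
#' controls (experiment 1), pseudoconditioning controls (experiment 2),
#' paired vs explicitly unpaired noise-shock (experiment 3), and prior
#' habituation to the noise (experiment 4). Conventions shared by all
#' designs: 5 trials per training/habituation day, a 1 s shock US, 10 s
#' auditory CSs (20 s tone for the stimulus-change group), intertrial
#' intervals drawn uniformly from 150-210 s (mean 180 s), and test days of
#' 16 trials (experiments 1-2), 2 trials (experiment 3), or 3 trials
#' (experiment 4).
#'
#' Group labels per experiment (case-insensitive; spaces/dashes tolerated):
#' \describe{
#'   \item{1}{`replication`, `cs_duration`, `stimulus_change`}
#'   \item{2}{`shock_only_noise_test`, `shock_only_tone_test`, `no_shock`,
#'     `paired_noise`}
#'   \item{3}{`paired`, `unpaired`, `cs_only`, `shock_only`}
#'   \item{4}{`h_shock`, `h_paired`, `c_shock`, `c_paired`}
#' }
#'
#' @param experiment Integer 1-4.
#' @param group Group label (see Details).
#' @param iti Intertrial interval: length-2 range for uniform draws (default
#'   `c(150, 210)`) or a single fixed value.
#' @param seed Optional integer; when given, ITI draws are reproducible.
#' @return A named list of [event_schedule()] objects, one per day, with a
#'   `phase` attribute on each (`"habituation"`, `"training"`, or `"test"`).
#' @examples
#' d <- make_design(1, "replication", iti = 180)
#' names(d)
#' d$test
#' @export
make_design <- function(experiment, group, iti = c(150, 210), seed = NULL) {
  if (!is_scalar_number(experiment) || !experiment %in% 1:4) {
    stop("`experiment` must be 1, 2, 3, or 4", call. = FALSE)
  }
  experiment <- as.integer(experiment)
  group <- normalize_group(group)
  groups <- design_groups(experiment)
  if (!group %in% groups) {
    stop(sprintf("configuration error: unknown group '%s' for experiment %d (expected one of: %s)",
                 group, experiment, paste(groups, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  stim <- function(...) {
    s <- list(...)
    data.frame(kind = vapply(s, `[[`, "", 1),
               duration = as.numeric(vapply(s, `[[`, "", 2)))
  }
  compound <- stim(c("tone", 10), c("noise", 10), c("shock", 1))
  compound_test <- stim(c("tone", 10), c("noise", 10))
  noise_shock <- stim(c("noise", 10), c("shock", 1))
  noise_only <- stim(c("noise", 10))
  tone_only <- stim(c("tone", 10))
  tone20_shock <- stim(c("tone", 20), c("shock", 1))
  shock_only <- stim(c("shock", 1))

  day <- function(stimuli, n, phase) {
    sched <- build_schedule(stimuli, n_trials = n, iti = iti)
    attr(sched, "phase") <- phase
    sched
  }
  # Context-exposure day matched in length to the other groups' sessions
  # (17 min 15 s).
  context_day <- function(phase) {
    sched <- event_schedule(NULL, session_length = 1035)
    attr(sched, "phase") <- phase
    sched
  }
  train <- function(stimuli) list(day1 = day(stimuli, 5, "training"),
                                  day2 = day(stimuli, 5, "training"))
  test1 <- function(stimuli, n) list(test = day(stimuli, n, "test"))

  days <- switch(
    paste(experiment, group, sep = "."),
    "1.replication" = c(train(compound), test1(compound_test, 16)),
    "1.cs_duration" = c(train(noise_shock), test1(noise_only, 16)),
    "1.stimulus_change" = c(train(tone20_shock), test1(compound_test, 16)),
    "2.shock_only_noise_test" = c(train(shock_only), test1(noise_only, 16)),
    "2.shock_only_tone_test" = c(train(shock_only), test1(tone_only, 16)),
    "2.no_shock" = c(list(day1 = context_day("training"),
                          day2 = context_day("training")),
                     test1(noise_only, 16)),
    "2.paired_noise" = c(train(noise_shock), test1(noise_only, 16)),
    "3.paired" = c(train(noise_shock), test1(noise_only, 2)),
    "3.unpaired" = list(day1 = unpaired_day(iti), day2 = unpaired_day(iti),
                        test = day(noise_only, 2, "test")),
    "3.cs_only" = c(train(noise_only), test1(noise_only, 2)),
    "3.shock_only" = c(train(shock_only), test1(noise_only, 2)),
    "4.h_shock" = c(hab_days(day, noise_only), train2(day, shock_only),
                    test1(noise_only, 3)),
    "4.h_paired" = c(hab_days(day, noise_only), train2(day, noise_shock),
                     test1(noise_only, 3)),
    "4.c_shock" = c(list(hab1 = context_day("habituation"),
                         hab2 = context_day("habituation")),
                    train2(day, shock_only), test1(noise_only, 3)),
    "4.c_paired" = c(list(hab1 = context_day("habituation"),
                          hab2 = context_day("habituation")),
                     train2(day, noise_shock), test1(noise_only, 3)),
    stop("unreachable"))
  days
}

hab_days <- function(day, stimuli) {
  list(hab1 = day(stimuli, 5, "habituation"),
       hab2 = day(stimuli, 5, "habituation"))
}

train2 <- function(day, stimuli) {
  list(day1 = day(stimuli, 5, "training"),
       day2 = day(stimuli, 5, "training"))
}

# Explicitly unpaired day: 5 noise and 5 shock presentations alternate, each
# separated from its neighbours by roughly half the nominal ITI, so noise
# never predicts shock.
unpaired_day <- function(iti) {
  half <- iti / 2
  gaps <- if (length(half) == 1L) rep(half, 9L) else stats::runif(9L, half[1], half[2])
  kinds <- rep(c("noise", "shock"), 5L)
  durs <- ifelse(kinds == "noise", 10, 1)
  onsets <- 180 + cumsum(c(0, gaps + durs[-10L]))
  ev <- data.frame(kind = kinds, onset = onsets, duration = durs,
                   trial_index = rep(1:5, each = 2L))
  sched <- event_schedule(ev, session_length = max(onsets + durs) + 60)
  attr(sched, "phase") <- "training"
  sched
}

normalize_group <- function(group) {
  g <- tolower(trimws(as.character(group)[1]))
  g <- gsub("[^a-z0-9]+", "_", g)
  g <- gsub("^_|_$", "", g)
  aliases <- c(
    "csduration" = "cs_duration",
    "stimuluschange" = "stimulus_change",
    "pseudoconditioned_noise" = "shock_only_noise_test",
    "pseudoconditioned_tone" = "shock_only_tone_test",
    "no_shock_control" = "no_shock",
    "noise_shock" = "paired_noise",
    "noise_shock_conditioning" = "paired_noise",
    "paired_noise_shock" = "paired",
    "unpaired_noise_shock" = "unpaired",
    "noise_cs_only" = "cs_only",
    "habituation_shock_only" = "h_shock",
    "habituation_paired_noise_shock" = "h_paired",
    "context_exposure_shock_only" = "c_shock",
    "context_exposure_paired_noise_shock" = "c_paired")
  if (g %in% names(aliases)) aliases[[g]] else g
}

design_groups <- function(experiment) {
  switch(experiment,
         c("replication", "cs_duration", "stimulus_change"),
         c("shock_only_noise_test", "shock_only_tone_test", "no_shock",
           "paired_noise"),
         c("paired", "unpaired", "cs_only", "shock_only"),
         c("h_shock", "h_paired", "c_shock", "c_paired"))
}
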