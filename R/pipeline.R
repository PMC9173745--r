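#' Score a session into per-trial, per-period metrics
#'
#' Runs the full scoring pipeline on one session: freezing bouts from the
#' activity trace, darts from the velocity trace, then per-trial segmentation
#' into prestim / stimulus / shock / post periods with percent freezing, peak
#' activity ratio, and dart rate for each period. This per-(subject, trial,
#' period) table is the unit of statistical analysis.
#'
#' PAR conventions: the During window is the stimulus (or shock) period; the
#' PreStim window is the equal-duration window immediately preceding that
#' period's onset (for the first CS of a trial this is chamber baseline; for
#' the second component of a serial compound it is the preceding component).
#'
#' @param velocity A [velocity_trace()] or a `sim_session` (in which case
#'   `activity` is taken from it).
#' @param activity An [activity_trace()] of the same session.
#' @param schedule The session's [event_schedule()].
#' @param freeze_threshold Activity threshold for freezing (see
#'   [score_freezing()]).
#' @param dart_threshold Minimum dart peak velocity, cm/s (default 22.9).
#' @param min_interpeak Minimum dart separation, s (default 0.8).
#' @param min_bout Minimum freezing bout, s (default 1).
#' @param prestim Pre-stimulus window length, s (default 10).
#' @return A list of class `scored_session`:
#'   \describe{
#'     \item{metrics}{tibble with `subject_id`, `session_id`, `trial_index`,
#'       `period`, `percent_freezing`, `par`, `darts_per_min`, `n_darts`.}
#'     \item{darts}{tibble of dart events with `period_kind`,
#'       `latency_from_onset`, `timing_class`, `ordinal_in_stimulus` filled
#'       in for darts inside stimulus periods.}
#'     \item{bouts}{the freezing bouts.}
#'   }
#' @export
score_session <- function(velocity, activity = NULL, schedule,
                          freeze_threshold = 18,
                          dart_threshold = 22.9, min_interpeak = 0.8,
                          min_bout = 1.0, prestim = 10) {
  if (inherits(velocity, "sim_session")) {
    activity <- velocity$activity
    velocity <- velocity$velocity
  }
  stopifnot(inherits(velocity, "velocity_trace"),
            inherits(activity, "activity_trace"),
            inherits(schedule, "event_schedule"))

  bouts <- score_freezing(activity, freeze_threshold, min_bout)
  darts <- detect_darts(velocity, dart_threshold, min_interpeak)
  darts$trial_index <- rep(NA_integer_, nrow(darts))

  trial_ids <- if (nrow(schedule$events)) {
    sort(unique(schedule$events$trial_index[schedule$events$kind != "context_only"]))
  } else integer()

  m_trial <- integer(); m_period <- character()
  m_frz <- numeric(); m_par <- numeric(); m_dpm <- numeric(); m_nd <- integer()
  for (k in trial_ids) {
    periods <- segment_trial(schedule, k, prestim = prestim)
    first_onset <- periods[[2]][1]  # first event of the trial
    for (pn in names(periods)) {
      w <- periods[[pn]]
      base_kind <- sub("\\.[0-9]+$", "", pn)
      in_p <- darts$time >= w[1] - .time_tol & darts$time < w[2] - .time_tol
      par_val <- NA_real_
      if (base_kind %in% c("tone", "noise", "shock")) {
        dur <- window_length(w)
        ps_win <- if (base_kind == "shock") {
          c(first_onset - dur, first_onset)
        } else {
          c(w[1] - dur, w[1])
        }
        if (ps_win[1] >= activity$t0 - .time_tol) {
          par_val <- compute_par(activity, during = w, prestim = ps_win)$value
        }
        if (any(in_p) && base_kind %in% c("tone", "noise")) {
          idx <- which(in_p)
          idx <- idx[order(darts$time[idx])]
          darts$period_kind[idx] <- base_kind
          darts$latency_from_onset[idx] <- darts$time[idx] - w[1]
          darts$timing_class[idx] <-
            classify_dart_timing(darts$time[idx], cs_onset = w[1],
                                 cs_duration = dur)
          darts$ordinal_in_stimulus[idx] <- seq_along(idx)
          darts$trial_index[idx] <- k
        } else if (any(in_p)) {
          darts$period_kind[which(in_p)] <- base_kind
          darts$trial_index[which(in_p)] <- k
        }
      } else if (any(in_p)) {
        darts$period_kind[which(in_p)] <- base_kind
        darts$trial_index[which(in_p)] <- k
      }
      m_trial <- c(m_trial, k)
      m_period <- c(m_period, pn)
      m_frz <- c(m_frz, percent_freezing(bouts, w))
      m_par <- c(m_par, par_val)
      m_dpm <- c(m_dpm, darts_per_minute(darts, w))
      m_nd <- c(m_nd, sum(in_p))
    }
  }
  darts$period_kind[is.na(darts$period_kind)] <- "baseline"
  darts <- tibble::as_tibble(cbind(
    data.frame(subject_id = rep(velocity$subject_id, nrow(darts)),
               session_id = rep(velocity$session_id, nrow(darts)),
               stringsAsFactors = FALSE),
    darts))
  metrics <- tibble::tibble(
    subject_id = rep(velocity$subject_id, length(m_trial)),
    session_id = rep(velocity$session_id, length(m_trial)),
    trial_index = m_trial, period = m_period,
    percent_freezing = m_frz, par = m_par,
    darts_per_min = m_dpm, n_darts = m_nd)
  structure(list(metrics = metrics, darts = darts, bouts = bouts),
            class = "scored_session")
}

#' @export
print.scored_session <- function(x, ...) {
  cat(sprintf("<scored session> %d trial-period rows, %d darts, %d freezing bouts\n",
              nrow(x$metrics), nrow(x$darts), nrow(x$bouts)))
  print(utils::head(x$metrics, 8))
  invisible(x)
}

#' Score every synthesized session of a cohort
#'
#' Convenience wrapper running [score_session()] over the output of
#' [simulate_cohort()] and row-binding the results, with `group`, `day`, and
#' `phase` columns added.
#'
#' @param cohort Output of [simulate_cohort()] (each subject carries its own
#'   per-day design, since ITIs are drawn per subject).
#' @param group Group label stamped on the rows.
#' @inheritParams score_session
#' @return A list with `metrics` and `darts` tibbles pooled over subjects
#'   and days.
#' @export
score_cohort <- function(cohort, group = "group",
                         freeze_threshold = 18, dart_threshold = 22.9,
                         min_interpeak = 0.8, min_bout = 1.0, prestim = 10) {
  all_metrics <- list()
  all_darts <- list()
  for (si in seq_along(cohort)) {
    subj <- cohort[[si]]
    des <- subj$design
    for (day_name in names(subj$sessions)) {
      sched <- des[[day_name]]
      sc <- score_session(subj$sessions[[day_name]], schedule = sched,
                          freeze_threshold = freeze_threshold,
                          dart_threshold = dart_threshold,
                          min_interpeak = min_interpeak,
                          min_bout = min_bout, prestim = prestim)
      phase <- attr(sched, "phase") %||% NA_character_
      sc$metrics$group <- group
      sc$metrics$day <- day_name
      sc$metrics$phase <- phase
      sc$darts$group <- group
      sc$darts$day <- day_name
      sc$darts$phase <- phase
      all_metrics[[length(all_metrics) + 1L]] <- sc$metrics
      all_darts[[length(all_darts) + 1L]] <- sc$darts
    }
  }
  list(metrics = do.call(rbind, all_metrics),
       darts = do.call(rbind, all_darts))
}
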