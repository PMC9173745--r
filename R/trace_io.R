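#' Construct a velocity trace
#'
#' A velocity trace is a uniformly sampled record of an animal's speed (cm/s),
#' as exported by center-point video tracking. Sample `i` (1-based) is located
#' at time `t0 + (i - 1) / sampling_rate` seconds from session start; all
#' analysis windows are half-open `[start, end)`.
#'
#' @param samples Numeric vector of non-negative speeds, cm/s.
#' @param sampling_rate Sampling rate in Hz (default 3.75, the nominal rate of
#'   center-point tracking exports).
#' @param subject_id,session_id Identifiers carried through scored outputs.
#' @param t0 Session-clock time of the first sample, seconds.
#' @return An object of class `velocity_trace`.
#' @examples
#' tr <- velocity_trace(c(0, 1, 2), sampling_rate = 3.75)
#' trace_times(tr)
#' @export
velocity_trace <- function(samples, sampling_rate = 3.75,
                           subject_id = "s1", session_id = "ses1", t0 = 0) {
  new_trace(samples, sampling_rate, subject_id, session_id, t0,
            class = "velocity_trace", what = "velocity sample")
}

#' Construct a frame-activity trace
#'
#' An activity trace holds per-frame motion scores (arbitrary units of pixel
#' change between adjacent video frames) at a nominal 30 frames/s. The time
#' convention is identical to [velocity_trace()].
#'
#' @param scores Numeric vector of non-negative activity scores.
#' @param frame_rate Frames per second (default 30).
#' @inheritParams velocity_trace
#' @return An object of class `activity_trace`.
#' @export
activity_trace <- function(scores, frame_rate = 30,
                           subject_id = "s1", session_id = "ses1", t0 = 0) {
  new_trace(scores, frame_rate, subject_id, session_id, t0,
            class = "activity_trace", what = "activity score")
}

new_trace <- function(samples, rate, subject_id, session_id, t0, class, what) {
  stopifnot_scalar(rate, "sampling rate", positive = TRUE)
  stopifnot_scalar(t0, "t0")
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("trace must contain at least one sample", call. = FALSE)
  bad <- which(!is.finite(samples) | samples < 0)
  if (length(bad)) {
    stop(sprintf("invalid %s at row %d: values must be finite and >= 0",
                 what, bad[1]), call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id)[1],
         session_id = as.character(session_id)[1],
         rate = rate, t0 = t0, samples = samples),
    class = c(class, "behavior_trace"))
}

#' @export
print.behavior_trace <- function(x, ...) {
  kind <- if (inherits(x, "velocity_trace")) "velocity" else "activity"
  cat(sprintf("<%s trace> subject %s, session %s: %d samples at %g Hz, t0 = %g s (%.1f s)\n",
              kind, x$subject_id, x$session_id, length(x$samples), x$rate,
              x$t0, length(x$samples) / x$rate))
  invisible(x)
}

#' Sample times of a trace
#'
#' @param trace A [velocity_trace()] or [activity_trace()].
#' @return Numeric vector of sample times in seconds from session start.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "behavior_trace"))
  trace$t0 + (seq_along(trace$samples) - 1) / trace$rate
}

# Indices of samples whose time falls in the half-open window [start, end).
# Computed arithmetically: sample i sits at t0 + (i - 1)/rate, so the window
# maps to a contiguous index range.
samples_in_window <- function(trace, window) {
  window <- as_window(window)
  n <- length(trace$samples)
  a <- (window[1] - trace$t0) * trace$rate
  b <- (window[2] - trace$t0) * trace$rate
  i_min <- max(1L, as.integer(ceiling(a - 1e-9)) + 1L)
  i_max <- min(n, as.integer(ceiling(b - 1e-9)))
  if (i_max < i_min) integer() else seq.int(i_min, i_max)
}

#' Read a locomotion trace from a delimited text export
#'
#' The format is a small `# key: value` header block (subject_id, session_id,
#' kind, sampling_rate, t0) followed by one numeric sample per row. This is
#' the package's stable interchange format for tracking-software exports;
#' adapting a particular vendor layout to it is a one-off reshaping step left
#' to the user.
#'
#' @param path File to read.
#' @param kind `"velocity"` or `"activity"`; checked against the file header
#'   when the header declares a kind.
#' @param delim Field delimiter; comma by default, tab accepted. Only the
#'   first field of each data row is used.
#' @return A [velocity_trace()] or [activity_trace()].
#' @export
read_trace <- function(path, kind = c("velocity", "activity"), delim = ",") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_hdr <- grepl("^\\s*#", lines)
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr]
  body <- body[nzchar(trimws(body))]

  meta <- list()
  for (h in hdr) {
    h <- sub("^\\s*#\\s*", "", h)
    kv <- regmatches(h, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(kv) == 3) meta[[kv[2]]] <- trimws(kv[3])
  }
  if (!is.null(meta$kind) && !identical(meta$kind, kind)) {
    stop(sprintf("file declares kind '%s' but '%s' was requested",
                 meta$kind, kind), call. = FALSE)
  }
  rate_key <- if (kind == "velocity") "sampling_rate" else "frame_rate"
  rate_str <- meta[[rate_key]] %||% meta$sampling_rate %||% meta$rate
  if (is.null(rate_str)) {
    stop(sprintf("format error: missing %s in header", rate_key), call. = FALSE)
  }
  rate <- suppressWarnings(as.numeric(rate_str))
  if (is.na(rate) || rate <= 0) {
    stop(sprintf("format error: %s must be a positive number, got '%s'",
                 rate_key, rate_str), call. = FALSE)
  }
  t0 <- suppressWarnings(as.numeric(meta$t0 %||% "0"))
  if (is.na(t0)) stop("format error: t0 is not numeric", call. = FALSE)

  # Drop a single non-numeric first row (column header).
  first_field <- function(x) trimws(vapply(strsplit(x, delim, fixed = TRUE),
                                           function(f) f[1], character(1)))
  vals_chr <- first_field(body)
  if (length(vals_chr) &&
      is.na(suppressWarnings(as.numeric(vals_chr[1]))) &&
      grepl("^[A-Za-z]", vals_chr[1])) {
    vals_chr <- vals_chr[-1]
  }
  if (!length(vals_chr)) stop("parse error: no data rows", call. = FALSE)
  vals <- suppressWarnings(as.numeric(vals_chr))
  if (anyNA(vals)) {
    stop(sprintf("parse error: non-numeric sample at data row %d ('%s')",
                 which(is.na(vals))[1], vals_chr[which(is.na(vals))[1]]),
         call. = FALSE)
  }
  neg <- which(vals < 0)
  if (length(neg)) {
    stop(sprintf("parse error: negative sample at data row %d", neg[1]),
         call. = FALSE)
  }
  ctor <- if (kind == "velocity") velocity_trace else activity_trace
  ctor(vals, rate,
       subject_id = meta$subject_id %||% "s1",
       session_id = meta$session_id %||% "ses1",
       t0 = t0)
}

#' Write a locomotion trace to the delimited text format
#'
#' Round-trips bit-exactly through [read_trace()] (samples are written with
#' full double precision).
#'
#' @param trace A [velocity_trace()] or [activity_trace()].
#' @param path Output file.
#' @param delim Field delimiter (single column, so only cosmetic).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, delim = ",") {
  stopifnot(inherits(trace, "behavior_trace"))
  kind <- if (inherits(trace, "velocity_trace")) "velocity" else "activity"
  rate_key <- if (kind == "velocity") "sampling_rate" else "frame_rate"
  hdr <- c(
    sprintf("# subject_id: %s", trace$subject_id),
    sprintf("# session_id: %s", trace$session_id),
    sprintf("# kind: %s", kind),
    sprintf("# %s: %s", rate_key, format(trace$rate, digits = 17)),
    sprintf("# t0: %s", format(trace$t0, digits = 17)),
    "sample")
  writeLines(c(hdr, format(trace$samples, digits = 17, trim = TRUE,
                           scientific = FALSE)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

event_kinds <- c("tone", "noise", "shock", "context_only")

#' Construct an event schedule
#'
#' An event schedule is the typed list of stimulus and shock events that
#' defines a session's trial structure: each event has a kind (`tone`,
#' `noise`, `shock`, or `context_only`), an onset and duration in seconds,
#' and the 1-based index of the trial it belongs to. Serial-compound trials
#' are contiguous: the noise starts at tone offset and the shock at noise
#' offset.
#'
#' @param events A data frame with columns `kind`, `onset`, `duration`,
#'   `trial_index`. May have zero rows (a context-exposure session).
#' @param session_length Total session length, seconds.
#' @return An object of class `event_schedule`.
#' @export
event_schedule <- function(events, session_length) {
  stopifnot_scalar(session_length, "session_length", positive = TRUE)
  if (is.null(events) || nrow(as.data.frame(events)) == 0L) {
    events <- data.frame(kind = character(), onset = numeric(),
                         duration = numeric(), trial_index = integer())
  }
  events <- as.data.frame(events)[, c("kind", "onset", "duration", "trial_index")]
  events$kind <- as.character(events$kind)
  events$onset <- as.numeric(events$onset)
  events$duration <- as.numeric(events$duration)
  events$trial_index <- as.integer(events$trial_index)

  if (nrow(events)) {
    if (!all(events$kind %in% event_kinds)) {
      stop(sprintf("unknown event kind(s): %s",
                   paste(setdiff(events$kind, event_kinds), collapse = ", ")),
           call. = FALSE)
    }
    if (any(events$duration <= 0 & events$kind != "context_only")) {
      stop("validation error: events must have duration > 0 (except context_only)",
           call. = FALSE)
    }
    if (any(events$trial_index < 1L) || anyNA(events$trial_index)) {
      stop("validation error: trial_index must be a positive integer", call. = FALSE)
    }
    events <- events[order(events$onset), , drop = FALSE]
    rownames(events) <- NULL
    off <- events$onset + events$duration
    if (any(events$onset < -.time_tol) ||
        any(off > session_length + .time_tol)) {
      stop("validation error: events must lie within [0, session_length)",
           call. = FALSE)
    }
    if (nrow(events) > 1L) {
      gap <- events$onset[-1] - off[-nrow(events)]
      if (any(gap < -.time_tol)) {
        i <- which(gap < -.time_tol)[1]
        stop(sprintf("validation error: event %d (%s) overlaps event %d (%s)",
                     i + 1L, events$kind[i + 1L], i, events$kind[i]),
             call. = FALSE)
      }
    }
  }
  structure(list(events = events, session_length = session_length),
            class = "event_schedule")
}

#' @export
print.event_schedule <- function(x, ...) {
  cat(sprintf("<event schedule> %d events, %d trial(s), session %g s\n",
              nrow(x$events),
              if (nrow(x$events)) length(unique(x$events$trial_index)) else 0L,
              x$session_length))
  if (nrow(x$events)) print(utils::head(x$events, 12))
  invisible(x)
}

#' Build a trial-structured schedule
#'
#' Lays out `n_trials` identical trials, each a contiguous serial chain of
#' stimuli (e.g. 10 s tone, then 10 s noise, then 1 s shock), separated by
#' intertrial intervals. The ITI is the gap between the last event offset of
#' one trial and the first onset of the next; the first trial starts
#' `baseline` seconds into the session.
#'
#' @param stimuli Data frame with columns `kind` and `duration` describing one
#'   trial, in order. Use `NULL` or zero rows for a context-exposure session.
#' @param n_trials Number of trials.
#' @param iti A single number for a fixed ITI, or a length-2 range from which
#'   ITIs are drawn uniformly (default `c(150, 210)`, mean 180 s). Draws use
#'   the current RNG state.
#' @param baseline Seconds before the first trial (default 180).
#' @param tail Seconds after the last event (default 60).
#' @return An [event_schedule()].
#' @examples
#' sched <- build_schedule(
#'   data.frame(kind = c("tone", "noise", "shock"), duration = c(10, 10, 1)),
#'   n_trials = 5, iti = 180)
#' @export
build_schedule <- function(stimuli, n_trials, iti = c(150, 210),
                           baseline = 180, tail = 60) {
  stopifnot_scalar(baseline, "baseline", positive = TRUE)
  stopifnot_scalar(tail, "tail", positive = TRUE)
  if (is.null(stimuli) || nrow(as.data.frame(stimuli)) == 0L || n_trials == 0L) {
    return(event_schedule(NULL, session_length = baseline + tail))
  }
  stimuli <- as.data.frame(stimuli)
  trial_dur <- sum(stimuli$duration)
  itis <- if (n_trials > 1L) {
    if (length(iti) == 1L) rep(iti, n_trials - 1L)
    else stats::runif(n_trials - 1L, min(iti), max(iti))
  } else numeric()
  trial_onsets <- baseline + cumsum(c(0, itis + trial_dur))
  ev <- do.call(rbind, lapply(seq_len(n_trials), function(k) {
    data.frame(kind = stimuli$kind,
               onset = trial_onsets[k] + cumsum(c(0, stimuli$duration))[seq_len(nrow(stimuli))],
               duration = stimuli$duration,
               trial_index = k)
  }))
  event_schedule(ev, session_length = trial_onsets[n_trials] + trial_dur + tail)
}

#' Read an event schedule from a YAML config
#'
#' Two layouts are accepted. A *literal* config lists `session_length` and
#' `events` (kind/onset/duration/trial_index each). A *trial spec* config
#' lists a `trial` block (ordered kind/duration stimuli), `n_trials`, and an
#' ITI rule (`iti: 180` fixed, or `iti: [150, 210]` drawn uniformly; supply
#' `seed` for a reproducible draw), plus optional `baseline` and `tail`.
#'
#' @param path YAML file.
#' @return An [event_schedule()].
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$events)) {
    ev <- do.call(rbind, lapply(cfg$events, function(e) {
      data.frame(kind = e$kind, onset = e$onset, duration = e$duration,
                 trial_index = e$trial_index)
    }))
    return(event_schedule(ev, session_length = cfg$session_length))
  }
  if (!is.null(cfg$trial)) {
    stim <- do.call(rbind, lapply(cfg$trial, function(s) {
      data.frame(kind = s$kind, duration = s$duration)
    }))
    if (!is.null(cfg$seed)) set.seed(cfg$seed)
    return(build_schedule(
      stim,
      n_trials = cfg$n_trials %||% 1L,
      iti = unlist(cfg$iti %||% c(150, 210)),
      baseline = cfg$baseline %||% 180,
      tail = cfg$tail %||% 60))
  }
  stop("format error: config must contain either `events` or `trial`",
       call. = FALSE)
}

#' Write an event schedule to a YAML config (literal layout)
#'
#' @param schedule An [event_schedule()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "event_schedule"))
  ev <- schedule$events
  cfg <- list(
    session_length = schedule$session_length,
    events = lapply(seq_len(nrow(ev)), function(i) {
      list(kind = ev$kind[i], onset = ev$onset[i],
           duration = ev$duration[i], trial_index = ev$trial_index[i])
    }))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
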