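#' Segment a trial into analysis periods
#'
#' Returns the half-open windows of one trial's analysis periods: the
#' pre-stimulus baseline (`prestim` seconds before the first event), each
#' stimulus period (`tone`, `noise`), the `shock` period, and a `post`
#' window after the last event. Periods are contiguous and non-overlapping;
#' periods a trial does not have (e.g. no tone in a noise-only trial) are
#' simply absent.
#'
#' @param schedule An [event_schedule()].
#' @param trial_index Trial to segment (1-based).
#' @param prestim Duration of the pre-stimulus window, seconds (default 10).
#' @param post Nominal duration of the post window, seconds (default 10);
#'   clipped to the session end and to the start of the next trial's
#'   pre-stimulus window.
#' @return Named list of length-2 numeric windows. Duplicate kinds within a
#'   trial get suffixes (`noise`, `noise.2`, ...).
#' @examples
#' sched <- build_schedule(
#'   data.frame(kind = c("tone", "noise", "shock"), duration = c(10, 10, 1)),
#'   n_trials = 2, iti = 180)
#' segment_trial(sched, 1)
#' @export
segment_trial <- function(schedule, trial_index, prestim = 10, post = 10) {
  stopifnot(inherits(schedule, "event_schedule"))
  ev <- schedule$events
  tr <- ev[ev$trial_index == trial_index & ev$kind != "context_only", ,
           drop = FALSE]
  if (nrow(tr) == 0L) {
    stop(sprintf("trial %s not found in schedule", trial_index), call. = FALSE)
  }
  tr <- tr[order(tr$onset), , drop = FALSE]
  first_onset <- tr$onset[1]
  last_offset <- max(tr$onset + tr$duration)

  periods <- list(prestim = c(max(0, first_onset - prestim), first_onset))
  kinds <- tr$kind
  names_k <- make.unique(kinds, sep = ".")
  for (i in seq_len(nrow(tr))) {
    periods[[names_k[i]]] <- c(tr$onset[i], tr$onset[i] + tr$duration[i])
  }
  nxt <- ev[ev$trial_index > trial_index & ev$kind != "context_only", ,
            drop = FALSE]
  post_end <- min(last_offset + post,
                  schedule$session_length,
                  if (nrow(nxt)) min(nxt$onset) - prestim else Inf)
  if (post_end > last_offset + .time_tol) {
    periods$post <- c(last_offset, post_end)
  }
  periods
}

#' Bin a velocity trace over a period
#'
#' Averages consecutive non-overlapping groups of `samples_per_bin` samples
#' within the half-open `period`; a trailing partial bin is dropped. At the
#' nominal 3.75 Hz sampling rate the default of 2 samples per bin gives the
#' conventional 0.533 s bins used for averaged velocity traces.
#'
#' @param trace A [velocity_trace()].
#' @param period Half-open window `c(start, end)`, seconds.
#' @param samples_per_bin Samples per bin (default 2).
#' @param align_to Time against which the bin grid is reported (default the
#'   period start; pass a CS onset to express alignment relative to it).
#' @return An object of class `binned_trace`: list with `bin_width` (s),
#'   `values` (mean velocity per bin, cm/s), `alignment` (time of bin 0
#'   relative to `align_to`, s), and `n_bins`.
#' @export
bin_trace <- function(trace, period, samples_per_bin = 2L, align_to = NULL) {
  stopifnot(inherits(trace, "velocity_trace"))
  period <- as_window(period, "period")
  if (!is_scalar_number(samples_per_bin) || samples_per_bin < 1 ||
      samples_per_bin != round(samples_per_bin)) {
    stop("`samples_per_bin` must be a positive integer", call. = FALSE)
  }
  samples_per_bin <- as.integer(samples_per_bin)
  i <- samples_in_window(trace, period)
  if (length(i) < samples_per_bin) {
    stop("validation error: period contains fewer samples than samples_per_bin",
         call. = FALSE)
  }
  n_bins <- length(i) %/% samples_per_bin
  use <- i[seq_len(n_bins * samples_per_bin)]
  vals <- colMeans(matrix(trace$samples[use], nrow = samples_per_bin))
  t_first <- trace_times(trace)[use[1]]
  align_to <- align_to %||% period[1]
  structure(list(bin_width = samples_per_bin / trace$rate,
                 values = as.numeric(vals),
                 alignment = t_first - align_to,
                 n_bins = n_bins),
            class = "binned_trace")
}

#' Average binned traces across trials
#'
#' Element-wise mean of one subject's per-trial binned traces (the averaging
#' order is trials within subject, then subjects within group; see
#' [within_subject_se()]).
#'
#' @param binned A list of `binned_trace` objects with identical bin
#'   structure.
#' @return A single `binned_trace`.
#' @export
average_trials <- function(binned) {
  if (inherits(binned, "binned_trace")) return(binned)
  stopifnot(is.list(binned), length(binned) >= 1L)
  b1 <- binned[[1]]
  for (b in binned) {
    if (!inherits(b, "binned_trace") || b$n_bins != b1$n_bins ||
        abs(b$bin_width - b1$bin_width) > 1e-9) {
      stop("validation error: binned traces have mismatched bin structure",
           call. = FALSE)
    }
  }
  vals <- rowMeans(matrix(unlist(lapply(binned, `[[`, "values")),
                          nrow = b1$n_bins))
  structure(list(bin_width = b1$bin_width, values = as.numeric(vals),
                 alignment = b1$alignment, n_bins = b1$n_bins),
            class = "binned_trace")
}

#' @export
print.binned_trace <- function(x, ...) {
  cat(sprintf("<binned trace> %d bins of %.4g s (bin 0 at %+.3g s)\n",
              x$n_bins, x$bin_width, x$alignment))
  print(utils::head(round(x$values, 3), 10))
  invisible(x)
}

#' Within-subject-corrected standard errors per bin
#'
#' Error bars for repeated-measures trace averages, corrected for
#' between-subject variability: each subject's row is normalized by
#' subtracting its own mean and adding the grand mean (removing subject
#' offsets), the per-bin sample SD of the normalized values is inflated by
#' `sqrt(C / (C - 1))` with `C` the number of bins (the bias correction for
#' the normalization), and the SE is that corrected SD divided by
#' `sqrt(n_subjects)`. Rows that differ only by additive offsets therefore
#' yield SE exactly 0.
#'
#' @param subject_by_bin Numeric matrix, subjects in rows, bins in columns
#'   (at least 2 of each).
#' @return Numeric vector of per-bin corrected SEs.
#' @examples
#' m <- rbind(c(1, 3), c(5, 5))
#' within_subject_se(m)  # 0.7071 in both bins
#' @export
within_subject_se <- function(subject_by_bin) {
  m <- as.matrix(subject_by_bin)
  if (!is.numeric(m) || nrow(m) < 2L || ncol(m) < 2L) {
    stop("validation error: need a numeric matrix with >= 2 subjects and >= 2 bins",
         call. = FALSE)
  }
  n <- nrow(m)
  C <- ncol(m)
  norm <- m - rowMeans(m) + mean(m)
  sds <- apply(norm, 2, stats::sd)
  sds * sqrt(C / (C - 1)) / sqrt(n)
}

#' Group-level averaged trace with corrected error bars
#'
#' Averages subject-level binned traces (one per subject, themselves averages
#' over trials; see [average_trials()]) into a group mean trace with
#' within-subject-corrected SEs.
#'
#' @param subject_traces List of `binned_trace` objects, one per subject.
#' @param group Group label.
#' @return A tibble with columns `group`, `bin`, `time` (bin start relative
#'   to the alignment point), `mean`, `se`, `n_subjects`.
#' @export
group_trace_summary <- function(subject_traces, group = "group") {
  stopifnot(is.list(subject_traces), length(subject_traces) >= 2L)
  b1 <- subject_traces[[1]]
  m <- t(vapply(subject_traces, `[[`, numeric(b1$n_bins), "values"))
  tibble::tibble(
    group = group,
    bin = seq_len(b1$n_bins),
    time = b1$alignment + (seq_len(b1$n_bins) - 1L) * b1$bin_width,
    mean = colMeans(m),
    se = within_subject_se(m),
    n_subjects = nrow(m))
}

#' Plot group-averaged velocity traces
#'
#' Simple line plot (mean ± corrected SE ribbon) of one or more
#' [group_trace_summary()] tables.
#'
#' @param summaries A data frame from [group_trace_summary()], or several
#'   row-bound together.
#' @return A ggplot object.
#' @export
plot_group_traces <- function(summaries) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_group_traces() requires ggplot2", call. = FALSE)
  }
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = time, y = mean,
                               colour = group, fill = group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - se, ymax = mean + se),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time from alignment point (s)",
                  y = "Velocity (cm/s)", colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
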