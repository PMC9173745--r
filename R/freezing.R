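#' Score freezing bouts from a frame-activity trace
#'
#' Freezing is complete immobility except respiration. It is scored from the
#' per-frame activity signal: an animal is freezing whenever its activity
#' score stays strictly below `threshold` for at least `min_bout` seconds.
#' Bout boundaries snap to frame times: a maximal run of `k` consecutive
#' sub-threshold frames at frame rate `r` is a bout of duration `k / r`, and
#' a run of exactly `min_bout * r` frames (e.g. 30 frames at 30 frames/s for
#' the default 1 s minimum) is included.
#'
#' The strict inequality (`score < threshold` counts as immobile) follows the
#' usual reading of an activity *threshold for freezing*; pass a slightly
#' larger threshold if your scoring convention is `<=`.
#'
#' @param trace An [activity_trace()].
#' @param threshold Activity threshold (same units as the trace scores);
#'   must be positive. The value is software- and rig-specific and should be
#'   calibrated against hand scoring.
#' @param min_bout Minimum bout duration in seconds (default 1).
#' @return A data frame of class `freezing_bouts` with columns `start` and
#'   `end` (seconds, half-open `[start, end)`), disjoint and ordered.
#' @examples
#' tr <- activity_trace(c(rep(1, 45), rep(50, 15)), frame_rate = 30)
#' score_freezing(tr, threshold = 10)
#' @export
score_freezing <- function(trace, threshold, min_bout = 1.0) {
  if (!inherits(trace, "activity_trace")) {
    stop("`trace` must be an activity_trace", call. = FALSE)
  }
  stopifnot_scalar(threshold, "threshold", positive = TRUE)
  stopifnot_scalar(min_bout, "min_bout", positive = TRUE)
  if (length(trace$samples) == 0L) {
    stop("validation error: empty trace", call. = FALSE)
  }
  below <- trace$samples < threshold
  r <- rle(below)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  keep <- r$values & (r$lengths / trace$rate >= min_bout - .time_tol)
  tt <- trace_times(trace)
  out <- data.frame(
    start = tt[starts_i[keep]],
    end = tt[starts_i[keep]] + r$lengths[keep] / trace$rate)
  class(out) <- c("freezing_bouts", "data.frame")
  out
}

#' Percent time freezing within a period
#'
#' The percentage of a half-open period `[start, end)` covered by freezing
#' bouts; bouts extending past the period boundary are clipped, so freezing
#' time is conserved across contiguous periods.
#'
#' @param bouts Output of [score_freezing()] (or any data frame with `start`
#'   and `end` columns).
#' @param period Length-2 numeric `c(start, end)`, seconds.
#' @return A percentage in `[0, 100]`.
#' @examples
#' bouts <- data.frame(start = 8, end = 12)
#' percent_freezing(bouts, c(0, 10))  # 20
#' @export
percent_freezing <- function(bouts, period) {
  period <- as_window(period, "period")
  if (is.null(bouts) || nrow(bouts) == 0L) return(0)
  covered <- sum(overlap_length(bouts$start, bouts$end, period[1], period[2]))
  100 * covered / window_length(period)
}
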