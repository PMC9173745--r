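# Internal helpers shared across modules.

# Half-open interval [start, end) as a length-2 numeric vector.
as_window <- function(w, what = "window") {
  if (!is.numeric(w) || length(w) != 2L || anyNA(w) || !all(is.finite(w))) {
    stop(sprintf("%s must be a finite numeric vector c(start, end)", what),
         call. = FALSE)
  }
  if (w[2] <= w[1]) {
    stop(sprintf("%s must be non-degenerate: end > start", what), call. = FALSE)
  }
  unname(as.numeric(w))
}

window_length <- function(w) w[2] - w[1]

# Length of the intersection of two half-open intervals.
overlap_length <- function(a_start, a_end, b_start, b_end) {
  pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# Tolerance used when comparing times that are sums of sample spacings.
.time_tol <- 1e-9

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is_scalar_number(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}
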