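# Independent brute-force oracles. These deliberately re-derive each
# quantity with naive scalar code, separate from the vectorized package
# implementations they check.

# All supra-threshold local-maximum candidate indices, plateaus counted once
# at their first sample: scan each index and compare against the nearest
# differing neighbours on each side.
oracle_dart_candidates <- function(v, threshold) {
  n <- length(v)
  out <- integer()
  for (i in seq_len(n)) {
    if (v[i] < threshold) next
    # first sample of its plateau?
    if (i > 1 && v[i - 1] == v[i]) next
    # nearest differing value to the left
    j <- i - 1
    while (j >= 1 && v[j] == v[i]) j <- j - 1
    left_ok <- j < 1 || v[j] < v[i]
    # nearest differing value to the right
    k <- i + 1
    while (k <= n && v[k] == v[i]) k <- k + 1
    right_ok <- k > n || v[k] < v[i]
    if (left_ok && right_ok) out <- c(out, i)
  }
  out
}

# Iterative suppression: repeatedly take the largest remaining candidate
# (earliest on ties), keep it, discard all remaining candidates closer than
# min_sep to it.
oracle_suppress <- function(times, mags, min_sep) {
  kept <- numeric(0)
  remaining <- seq_along(times)
  while (length(remaining)) {
    best <- remaining[order(-mags[remaining], times[remaining])][1]
    kept <- c(kept, best)
    remaining <- remaining[abs(times[remaining] - times[best]) >= min_sep - 1e-9 &
                             remaining != best]
  }
  sort(kept)
}

oracle_detect_darts <- function(v, rate, threshold, min_sep) {
  cand <- oracle_dart_candidates(v, threshold)
  tt <- (cand - 1) / rate
  cand[oracle_suppress(tt, v[cand], min_sep)]
}

# Run-length scan for freezing bouts.
oracle_freezing_bouts <- function(scores, rate, threshold, min_bout) {
  n <- length(scores)
  bouts <- NULL
  i <- 1
  while (i <= n) {
    if (scores[i] < threshold) {
      j <- i
      while (j < n && scores[j + 1] < threshold) j <- j + 1
      if ((j - i + 1) / rate >= min_bout - 1e-9) {
        bouts <- rbind(bouts, c((i - 1) / rate, j / rate))
      }
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(bouts)) bouts <- matrix(numeric(), ncol = 2)
  colnames(bouts) <- c("start", "end")
  bouts
}

# Linear-interpolation percentile at rank p/100 * (n - 1), 0-based.
oracle_percentile <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p / 100
  lo <- floor(h) + 1
  hi <- min(lo + 1, length(xs))
  xs[lo] + (h - floor(h)) * (xs[hi] - xs[lo])
}

# Textbook Welch ANOVA with weights n_i / s_i^2.
oracle_welch <- function(groups) {
  k <- length(groups)
  n <- lengths(groups)
  m <- vapply(groups, mean, 1)
  s2 <- vapply(groups, var, 1)
  w <- n / s2
  mw <- sum(w * m) / sum(w)
  num <- sum(w * (m - mw)^2) / (k - 1)
  lam <- sum((1 - w / sum(w))^2 / (n - 1))
  den <- 1 + 2 * (k - 2) / (k^2 - 1) * lam
  W <- num / den
  df2 <- (k^2 - 1) / (3 * lam)
  list(W = W, df1 = k - 1, df2 = df2,
       p = pf(W, k - 1, df2, lower.tail = FALSE))
}

# One-within-factor repeated-measures F from the explicit SS decomposition
# on a subjects x conditions matrix.
oracle_rm_F <- function(y) {
  n <- nrow(y); t <- ncol(y)
  grand <- mean(y)
  ss_cond <- n * sum((colMeans(y) - grand)^2)
  ss_subj <- t * sum((rowMeans(y) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  F <- (ss_cond / (t - 1)) / (ss_err / ((n - 1) * (t - 1)))
  list(F = F, df1 = t - 1, df2 = (n - 1) * (t - 1))
}

# Compact schedule used by simulation-heavy tests: two 10 s noise trials.
compact_noise_schedule <- function(n_trials = 2, iti = 60, baseline = 60,
                                   tail = 30) {
  build_schedule(data.frame(kind = "noise", duration = 10),
                 n_trials = n_trials, iti = iti, baseline = baseline,
                 tail = tail)
}

# Parameters with well-separated scales: clamped dart-free baseline, dart
# peaks far above threshold, deterministic-width darts.
separated_params <- function(...) {
  defaults <- list(baseline_mean_speed = 3, baseline_sd = 2,
                   baseline_clamp = 11, dart_peak_mean = 60, dart_peak_sd = 3,
                   shock_peak_mean = 80, shock_peak_sd = 5,
                   sensitization_gain = 0.1, habituation_decay = 1,
                   fear_freeze_slope = 0, context_fear_increment = 0,
                   late_dart_prob_paired = 0)
  do.call(behavior_params, utils::modifyList(defaults, list(...)))
}
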