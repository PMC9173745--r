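test_that("PAR follows During/(During + PreStim) with the 0.5 conventions", {
  # equal peaks in both windows -> 0.5 (no movement beyond baseline)
  tr <- activity_trace(c(rep(5, 30), rep(5, 30)), frame_rate = 30)
  expect_equal(compute_par(tr, c(1, 2), c(0, 1))$value, 0.5)

  # during peak 30 vs prestim peak 10 -> 0.75
  tr2 <- activity_trace(c(rep(10, 30), rep(30, 30)), frame_rate = 30)
  res <- compute_par(tr2, c(1, 2), c(0, 1))
  expect_equal(res$value, 0.75)
  expect_equal(res$during_peak, 30)
  expect_equal(res$prestim_peak, 10)

  # both windows all-zero -> defined degenerate 0.5
  tr3 <- activity_trace(rep(0, 60), frame_rate = 30)
  expect_equal(compute_par(tr3, c(1, 2), c(0, 1))$value, 0.5)
})

test_that("PAR validates its windows", {
  tr <- activity_trace(rep(1, 90), frame_rate = 30)
  expect_error(compute_par(tr, c(1, 3), c(0, 1)), "equal duration")
  expect_error(compute_par(tr, c(0, 1), c(1, 2)), "precede")
  expect_error(compute_par(tr, c(4, 5), c(3, 4)), "at least one sample")
})

test_that("PAR is within [0,1], increasing in the during peak, 0.5 iff equal", {
  prestim_scores <- rep(10, 30)
  vals <- sapply(c(5, 10, 20, 40, 80), function(pk) {
    tr <- activity_trace(c(prestim_scores, rep(1, 29), pk), frame_rate = 30)
    compute_par(tr, c(1, 2), c(0, 1))$value
  })
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(diff(vals) > 0))
  expect_equal(vals[2], 0.5)
  expect_true(all(vals[-2] != 0.5))
})

test_that("threshold derivation is the linear-interpolation percentile", {
  expect_equal(derive_dart_threshold(rep(7, 1000)), 7)
  x <- 0.01 * (1:10000)
  expect_equal(derive_dart_threshold(x), oracle_percentile(x, 99.5))
  expect_equal(derive_dart_threshold(x), 99.50005, tolerance = 1e-6)
  expect_equal(derive_dart_threshold(c(1, 2, 3), percentile = 100, min_n = 3), 3)
  expect_error(derive_dart_threshold(rnorm(50)), "22.9")
})

test_that("threshold derivation is monotone in percentile and scale-equivariant", {
  set.seed(31)
  x <- rexp(2000, 1 / 5)
  qs <- sapply(c(50, 90, 99, 99.5), derive_dart_threshold,
               baseline_samples = x)
  expect_true(all(diff(qs) > 0))
  expect_equal(derive_dart_threshold(3 * x), 3 * derive_dart_threshold(x))
  # oracle equivalence across random draws and percentiles
  for (p in c(25, 75, 99.5)) {
    expect_equal(derive_dart_threshold(x, p), oracle_percentile(x, p))
  }
})

test_that("dart detection finds isolated peaks and suppresses near pairs", {
  v <- rep(0, 9); v[5] <- 30
  d <- detect_darts(velocity_trace(v))
  expect_equal(nrow(d), 1)
  expect_equal(d$magnitude, 30)
  expect_equal(d$time, 4 / 3.75)

  # peaks 30 and 28 cm/s two samples (0.533 s) apart: keep the larger
  v2 <- rep(0, 9); v2[4] <- 30; v2[6] <- 28
  d2 <- detect_darts(velocity_trace(v2))
  expect_equal(nrow(d2), 1)
  expect_equal(d2$magnitude, 30)

  # sub-threshold trace: nothing
  expect_equal(nrow(detect_darts(velocity_trace(rep(10, 20)))), 0)

  # plateau counts once, at its first sample
  v3 <- c(0, 25, 25, 25, 0)
  d3 <- detect_darts(velocity_trace(v3))
  expect_equal(nrow(d3), 1)
  expect_equal(d3$time, 1 / 3.75)
})

test_that("suppression ties go to the earlier peak; spacing of 0.8 s is allowed", {
  # equal peaks 2 samples apart: earlier survives
  v <- rep(0, 9); v[4] <- 30; v[6] <- 30
  d <- detect_darts(velocity_trace(v))
  expect_equal(nrow(d), 1)
  expect_equal(d$time, 3 / 3.75)
  # exactly 3 samples = 0.8 s apart: both kept
  v2 <- rep(0, 9); v2[3] <- 30; v2[6] <- 28
  expect_equal(nrow(detect_darts(velocity_trace(v2))), 2)
})

test_that("dart detection equals the brute-force oracle on random traces", {
  set.seed(32)
  alphabet <- c(0, 20, 30)
  for (rep_i in 1:300) {
    n <- sample(2:50, 1)
    v <- sample(alphabet, n, replace = TRUE)
    got <- detect_darts(velocity_trace(v), threshold = 22.9, min_interpeak = 0.8)
    want <- oracle_detect_darts(v, 3.75, 22.9, 0.8)
    expect_equal(got$time, (want - 1) / 3.75)
    # spacing invariant
    if (nrow(got) > 1) expect_true(all(diff(got$time) >= 0.8 - 1e-9))
  }
})

test_that("darts_per_minute is 60 x count / period length", {
  d <- data.frame(time = c(1, 5, 9), magnitude = 30)
  expect_equal(darts_per_minute(d[1, ], c(0, 10)), 6)
  expect_equal(darts_per_minute(d[0, ], c(0, 10)), 0)
  expect_equal(darts_per_minute(d, c(0, 20)), 9)
  # the half-open boundary excludes a dart exactly at period end
  expect_equal(darts_per_minute(data.frame(time = 10), c(0, 10)), 0)
})

test_that("early/late classification uses the half-open 3 s boundary", {
  expect_equal(classify_dart_timing(0.27, 0), "early")
  expect_equal(classify_dart_timing(7.0, 0), "late")
  expect_equal(classify_dart_timing(3.0, 0), "late")
  expect_error(classify_dart_timing(10.0, 0), "classification error")
  expect_error(classify_dart_timing(-0.1, 0), "classification error")
  # the classes partition any in-window dart
  lat <- seq(0, 9.9, by = 0.3)
  cls <- classify_dart_timing(lat, 0)
  expect_true(all(cls %in% c("early", "late")))
  expect_equal(cls == "early", lat < 3)
})

test_that("multi-dart pairs take the first two darts per presentation", {
  darts <- data.frame(
    subject_id = c("a", "a", "a", "b", "b", "b"),
    trial_index = c(1, 1, 2, 1, 1, 1),
    period_kind = "noise",
    time = c(0.5, 4.0, 1.0, 0.5, 2.0, 5.0),
    magnitude = c(40, 25, 33, 50, 45, 30))
  pairs <- multi_dart_pairs(darts)
  expect_equal(nrow(pairs), 2)
  a <- pairs[pairs$subject_id == "a", ]
  expect_equal(c(a$first_magnitude, a$second_magnitude), c(40, 25))
  # three darts contribute only the first pair
  b <- pairs[pairs$subject_id == "b", ]
  expect_equal(c(b$first_magnitude, b$second_magnitude), c(50, 45))
  # single-dart presentations contribute nothing
  expect_equal(nrow(multi_dart_pairs(darts[1, ])), 0)
})

test_that("shock reactivity is the peak over shock + 1 s tail", {
  v <- rep(5, 40)
  v[20] <- 80  # during the shock second
  tr <- velocity_trace(v)
  expect_equal(shock_reactivity(tr, 4.8), 80)  # sample 20 sits at 5.07 s
  expect_equal(shock_reactivity(velocity_trace(rep(5, 40)), 2), 5)
  # a peak 0.5 s after shock offset is inside the extended window
  v2 <- rep(1, 40); v2[which.min(abs((0:39) / 3.75 - 3.5))] <- 44
  expect_equal(shock_reactivity(velocity_trace(v2), 2), 44)
  expect_error(shock_reactivity(velocity_trace(rep(1, 10)), 9), "outside trace")
})
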