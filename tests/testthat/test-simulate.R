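test_that("simulation is bit-identical under a fixed seed and decorrelated across seeds", {
  sched <- compact_noise_schedule()
  p <- behavior_params()
  st <- subject_state(n_shocks = 10, context_fear = 0.5)
  a <- simulate_session(sched, p, st, seed = 101)
  b <- simulate_session(sched, p, st, seed = 101)
  expect_identical(a$velocity$samples, b$velocity$samples)
  expect_identical(a$activity$samples, b$activity$samples)
  expect_identical(a$truth, b$truth)

  c_ <- simulate_session(sched, p, st, seed = 102)
  expect_false(identical(a$velocity$samples, c_$velocity$samples))
  expect_lt(abs(cor(a$velocity$samples, c_$velocity$samples)), 0.15)
})

test_that("ground truth obeys its invariants", {
  d <- make_design(1, "replication", iti = 180)
  p <- behavior_params()
  st <- subject_state()
  ses <- simulate_session(d$day1, p, st, seed = 7)
  tr <- ses$truth
  len <- d$day1$session_length
  expect_true(all(tr$dart_times >= 0 & tr$dart_times < len))
  expect_true(all(tr$dart_magnitudes > p$freeze_speed_ceiling))
  b <- tr$freezing_bouts
  if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  # inside bouts, velocity below the freeze ceiling and activity sub-threshold
  tt <- trace_times(ses$velocity)
  ta <- trace_times(ses$activity)
  for (i in seq_len(nrow(b))) {
    iv <- tt >= b$start[i] - 1e-9 & tt < b$end[i] - 1e-9
    ia <- ta >= b$start[i] - 1e-9 & ta < b$end[i] - 1e-9
    expect_true(all(ses$velocity$samples[iv] < p$freeze_speed_ceiling))
    expect_true(all(ses$activity$samples[ia] < p$activity_freeze_threshold))
  }
  # shocks always produce a recorded burst
  expect_equal(length(tr$shock_times), 5)
})

test_that("saturating fear makes the CS period fully frozen downstream", {
  sched <- compact_noise_schedule()
  p <- behavior_params(fear_freeze_slope = 1e6, sensitization_gain = 0,
                       late_dart_prob_paired = 0)
  st <- subject_state(pairings = c(tone = 0L, noise = 10L), context_fear = 0)
  ses <- simulate_session(sched, p, st, seed = 5)
  sc <- score_session(ses, schedule = sched,
                      freeze_threshold = p$activity_freeze_threshold)
  cs_rows <- sc$metrics[sc$metrics$period == "noise", ]
  expect_equal(cs_rows$percent_freezing, rep(100, 2))
})

test_that("injected well-separated darts are recovered exactly downstream", {
  sched <- build_schedule(data.frame(kind = "noise", duration = 10),
                          n_trials = 3, iti = 60, baseline = 60, tail = 30)
  p <- separated_params(dart_peak_mean = 35, dart_peak_sd = 0)
  st <- subject_state(n_shocks = 10L)  # p(dart) = 1 at every onset
  ses <- simulate_session(sched, p, st, seed = 8)
  expect_equal(length(ses$truth$dart_times), 3)
  expect_true(all(ses$truth$dart_magnitudes == 35))
  d <- detect_darts(ses$velocity, threshold = 22.9, min_interpeak = 0.8)
  expect_equal(nrow(d), 3)
  expect_equal(d$time, ses$truth$dart_times)
  expect_equal(d$magnitude, rep(35, 3))
})

test_that("onset-dart production is monotone in the sensitization gain", {
  sched <- compact_noise_schedule()
  gains <- c(0, 0.03, 0.06, 0.1)
  mean_counts <- sapply(gains, function(g) {
    p <- behavior_params(sensitization_gain = g, late_dart_prob_paired = 0)
    counts <- vapply(1:100, function(i) {
      st <- subject_state(n_shocks = 10L)
      length(simulate_session(sched, p, st, seed = 1000 + i)$truth$dart_times)
    }, 1)
    mean(counts)
  })
  expect_true(all(diff(mean_counts) >= 0))
  expect_gt(mean_counts[4], mean_counts[1])
})

test_that("state advancement counts shocks, exposures, and pairings", {
  p <- behavior_params()
  d <- make_design(1, "replication", iti = 180)
  st <- subject_state()
  st <- advance_state(st, d$day1, p)
  expect_equal(st$n_shocks, 5L)
  expect_equal(st$exposures[["tone"]], 5L)
  expect_equal(st$exposures[["noise"]], 5L)
  # in the serial compound only the noise is contiguous with shock
  expect_equal(st$pairings[["noise"]], 5L)
  expect_equal(st$pairings[["tone"]], 0L)
  expect_equal(st$context_fear, 5 * p$context_fear_increment)

  # unpaired day: exposures but no pairings
  du <- make_design(3, "unpaired", iti = 180)
  st2 <- advance_state(subject_state(), du$day1, p)
  expect_equal(st2$exposures[["noise"]], 5L)
  expect_equal(st2$pairings[["noise"]], 0L)
  expect_equal(st2$n_shocks, 5L)
})

test_that("state threading across days matches day-by-day advancement", {
  p <- behavior_params()
  d <- make_design(3, "paired", iti = 180)
  subj <- simulate_subject(d, p, seed = 3, synthesize_phases = "test")
  manual <- subject_state()
  for (day in d) manual <- advance_state(manual, day, p)
  expect_equal(subj$state, manual)
  # only the test day was synthesized
  expect_named(subj$sessions, "test")
})
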