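compound_sched <- function() {
  build_schedule(
    data.frame(kind = c("tone", "noise", "shock"), duration = c(10, 10, 1)),
    n_trials = 2, iti = 180)
}

test_that("segment_trial returns contiguous half-open periods", {
  p <- segment_trial(compound_sched(), 1)
  expect_equal(p$prestim, c(170, 180))
  expect_equal(p$tone, c(180, 190))
  expect_equal(p$noise, c(190, 200))
  expect_equal(p$shock, c(200, 201))
  expect_equal(p$post[1], 201)
  # contiguity
  ends <- sapply(p, `[`, 2)
  starts <- sapply(p, `[`, 1)
  expect_equal(unname(starts[-1]), unname(ends[-length(ends)]))
})

test_that("segments only contain the periods a trial has", {
  shock_only <- build_schedule(data.frame(kind = "shock", duration = 1),
                               n_trials = 2, iti = 180)
  p <- segment_trial(shock_only, 1)
  expect_false(any(c("tone", "noise") %in% names(p)))
  expect_true(all(c("prestim", "shock") %in% names(p)))

  noise_test <- build_schedule(data.frame(kind = "noise", duration = 10),
                               n_trials = 1, iti = 180)
  p2 <- segment_trial(noise_test, 1)
  expect_setequal(names(p2), c("prestim", "noise", "post"))
  expect_error(segment_trial(noise_test, 5), "not found")
})

test_that("post windows never reach into the next trial's prestim", {
  p <- segment_trial(compound_sched(), 1)
  nxt <- segment_trial(compound_sched(), 2)
  expect_lte(p$post[2], nxt$prestim[1])
})

test_that("bin_trace averages sample pairs and drops trailing partials", {
  tr <- velocity_trace(as.numeric(1:21), sampling_rate = 3.75)
  b <- bin_trace(tr, c(0, 21 / 3.75))
  expect_equal(b$bin_width, 2 / 3.75)            # 0.5333 s
  expect_equal(round(b$bin_width, 3), 0.533)
  expect_equal(b$n_bins, 10)                     # 21st sample dropped
  expect_equal(b$values, seq(1.5, 19.5, by = 2))

  b20 <- bin_trace(velocity_trace(rep(1, 20)), c(0, 20 / 3.75))
  expect_equal(b20$n_bins, 10)
  expect_error(bin_trace(velocity_trace(1:2), c(0, 0.1), samples_per_bin = 3),
               "fewer samples")
})

test_that("average_trials is the elementwise mean and validates structure", {
  tr <- function(v) bin_trace(velocity_trace(v), c(0, length(v) / 3.75))
  avg <- average_trials(list(tr(c(1, 1, 2, 2, 3, 3)), tr(c(3, 3, 4, 4, 5, 5))))
  expect_equal(avg$values, c(2, 3, 4))
  single <- tr(c(7, 7))
  expect_equal(average_trials(list(single))$values, single$values)
  expect_error(average_trials(list(tr(rep(0, 6)), tr(rep(0, 4)))),
               "mismatched bin structure")
})

test_that("binning then averaging trials commutes with averaging raw samples", {
  set.seed(41)
  raw <- replicate(4, rexp(20, 1 / 5), simplify = FALSE)
  per_trial <- lapply(raw, function(v) {
    bin_trace(velocity_trace(v), c(0, 20 / 3.75))
  })
  via_bins <- average_trials(per_trial)$values
  via_raw <- bin_trace(velocity_trace(Reduce(`+`, raw) / 4),
                       c(0, 20 / 3.75))$values
  expect_equal(via_bins, via_raw, tolerance = 1e-9)
})

test_that("within-subject SE removes subject offsets and matches the formula", {
  # parallel rows: pure additive offsets -> zero corrected SE
  m <- rbind(c(1, 2, 3), c(4, 5, 6), c(10, 11, 12))
  expect_equal(within_subject_se(m), c(0, 0, 0))

  # worked example: normalized rows (2.5,4.5),(3.5,3.5); SD .7071; x sqrt2 / sqrt2
  expect_equal(within_subject_se(rbind(c(1, 3), c(5, 5))),
               c(0.7071068, 0.7071068), tolerance = 1e-6)

  expect_equal(within_subject_se(matrix(5, 3, 4)), rep(0, 4))
  expect_error(within_subject_se(matrix(1, 1, 4)), ">= 2 subjects")
})

test_that("corrected SE is invariant to shifting one subject's whole row", {
  set.seed(42)
  m <- matrix(rnorm(24), 4, 6)
  m2 <- m
  m2[2, ] <- m2[2, ] + 100
  expect_equal(within_subject_se(m), within_subject_se(m2), tolerance = 1e-9)
  # normalization preserves per-bin means
  norm <- m - rowMeans(m) + mean(m)
  expect_equal(colMeans(norm), colMeans(m), tolerance = 1e-12)
})

test_that("group_trace_summary assembles mean and corrected SE per bin", {
  trs <- lapply(1:3, function(i) {
    bin_trace(velocity_trace(rep(i, 8)), c(0, 8 / 3.75))
  })
  g <- group_trace_summary(trs, group = "g1")
  expect_equal(nrow(g), 4)
  expect_equal(g$mean, rep(2, 4))
  expect_equal(g$se, rep(0, 4))   # parallel subjects
  expect_equal(g$n_subjects, rep(3L, 4))
})
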