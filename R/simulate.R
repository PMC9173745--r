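#' Parameters of the synthetic behavior generator
#'
#' Encodes a deliberately simple generative model of defensive behavior in a
#' fear-conditioning chamber, with the qualitative structure the scoring
#' pipeline assumes: autoregressive baseline locomotion; freezing bouts
#' (near-zero speed and sub-threshold activity) whose per-slot probability
#' grows with fear; onset-locked darts whose probability grows with shock
#' history (sensitization) and shrinks with stimulus familiarity
#' (habituation); an extra mid-CS dart in subjects with CS-US pairings; and
#' large reactivity bursts to every shock.
#'
#' Baseline speed is a stationary lognormal AR(1) process: `baseline_mean_speed`
#' is its median (cm/s) and `baseline_sd` its approximate marginal SD (cm/s),
#' mapped to the log scale by moment matching. The defaults (median 4,
#' SD 3.05) put the 99.5th percentile of pooled baseline speed near the
#' conventional 22.9 cm/s dart threshold; this is a convenience calibration,
#' not a measured distribution.
#'
#' @param baseline_mean_speed Median baseline speed, cm/s.
#' @param baseline_sd Approximate marginal SD of baseline speed, cm/s.
#' @param baseline_ar_coeff AR(1) coefficient of log-speed, in `[0, 1)`.
#' @param baseline_clamp Hard ceiling on baseline speed, cm/s (default `Inf`;
#'   set low to guarantee a dart-free baseline in recovery tests).
#' @param freeze_speed_ceiling Speed ceiling during freezing bouts, cm/s.
#' @param dart_peak_mean,dart_peak_sd Dart peak velocity distribution, cm/s
#'   (normal, truncated below at `freeze_speed_ceiling`).
#' @param dart_duration Dart width, s; darts are single-sample transients at
#'   the 3.75 Hz velocity resolution, with 1-sample shoulders when
#'   `dart_duration` spans 2+ samples.
#' @param late_dart_peak_frac Mean of mid-CS dart peaks relative to
#'   `dart_peak_mean` (late darts are slower than onset darts).
#' @param shock_peak_mean,shock_peak_sd Shock-reactivity burst peak, cm/s.
#' @param sensitization_gain Increment in onset-dart probability per prior
#'   shock.
#' @param habituation_decay Multiplicative decay of onset-dart probability
#'   per prior exposure to the same stimulus kind, in `(0, 1]`.
#' @param assoc_increment Fear-state increment per CS-US pairing.
#' @param fear_freeze_slope Maps fear state to the freezing probability of
#'   each generation slot (the smallest whole number of velocity samples
#'   spanning at least 1 s; 1.067 s at 3.75 Hz).
#' @param late_dart_prob_paired Probability of a second, mid-CS dart on each
#'   CS presentation in subjects with prior CS-US pairings.
#' @param context_fear_increment Context-fear increment per shock received.
#' @param activity_scale Activity units per cm/s in the activity transform.
#' @param activity_noise_sd SD of multiplicative lognormal frame noise.
#' @param activity_freeze_threshold Activity threshold separating freezing
#'   frames from movement frames; the generator keeps freezing frames below
#'   80% of it, and it is the natural scoring threshold for synthetic data.
#' @param sampling_rate Velocity sampling rate, Hz.
#' @param frame_rate Activity frame rate, frames/s; must be an integer
#'   multiple of `sampling_rate`.
#' @param seed Default RNG seed for [simulate_session()].
#' @return An object of class `behavior_params` (a validated list).
#' @export
behavior_params <- function(baseline_mean_speed = 4.0,
                            baseline_sd = 3.05,
                            baseline_ar_coeff = 0.6,
                            baseline_clamp = Inf,
                            freeze_speed_ceiling = 1.0,
                            dart_peak_mean = 35,
                            dart_peak_sd = 6,
                            dart_duration = 0.267,
                            late_dart_peak_frac = 0.75,
                            shock_peak_mean = 60,
                            shock_peak_sd = 10,
                            sensitization_gain = 0.08,
                            habituation_decay = 0.85,
                            assoc_increment = 0.06,
                            fear_freeze_slope = 0.9,
                            late_dart_prob_paired = 0.4,
                            context_fear_increment = 0.06,
                            activity_scale = 20,
                            activity_noise_sd = 0.1,
                            activity_freeze_threshold = 18,
                            sampling_rate = 3.75,
                            frame_rate = 30,
                            seed = 1L) {
  p <- as.list(environment())
  for (nm in c("baseline_mean_speed", "baseline_sd", "freeze_speed_ceiling",
               "dart_peak_mean", "dart_peak_sd", "shock_peak_mean",
               "shock_peak_sd", "activity_scale", "activity_freeze_threshold")) {
    if (!is_scalar_number(p[[nm]]) || p[[nm]] < 0) {
      stop(sprintf("`%s` must be a non-negative number", nm), call. = FALSE)
    }
  }
  for (nm in c("sensitization_gain", "assoc_increment", "fear_freeze_slope",
               "context_fear_increment")) {
    if (!is_scalar_number(p[[nm]]) || p[[nm]] < 0) {
      stop(sprintf("`%s` must be >= 0", nm), call. = FALSE)
    }
  }
  p$late_dart_prob_paired <- clamp01(p$late_dart_prob_paired)
  if (p$habituation_decay <= 0 || p$habituation_decay > 1) {
    stop("`habituation_decay` must be in (0, 1]", call. = FALSE)
  }
  if (p$baseline_ar_coeff < 0 || p$baseline_ar_coeff >= 1) {
    stop("`baseline_ar_coeff` must be in [0, 1)", call. = FALSE)
  }
  upsample <- p$frame_rate / p$sampling_rate
  if (abs(upsample - round(upsample)) > 1e-9) {
    stop("`frame_rate` must be an integer multiple of `sampling_rate`",
         call. = FALSE)
  }
  p$seed <- as.integer(seed)
  structure(p, class = "behavior_params")
}

#' Per-subject learning state
#'
#' Tracks the slowly evolving quantities the generator conditions on: number
#' of shocks received, per-stimulus exposure counts (habituation), per-CS
#' pairing counts (associative state), and scalar context fear. The state is
#' updated deterministically by the events of each session, so it can be
#' advanced across days without synthesizing traces (see [advance_state()]).
#'
#' @param n_shocks Shocks received so far.
#' @param exposures Named counts of prior exposures per stimulus kind.
#' @param pairings Named counts of prior CS-US pairings per stimulus kind.
#' @param context_fear Scalar context fear in `[0, 1]`.
#' @return An object of class `subject_state`.
#' @export
subject_state <- function(n_shocks = 0L,
                          exposures = c(tone = 0L, noise = 0L),
                          pairings = c(tone = 0L, noise = 0L),
                          context_fear = 0) {
  structure(list(n_shocks = as.integer(n_shocks),
                 exposures = exposures, pairings = pairings,
                 context_fear = clamp01(context_fear)),
            class = "subject_state")
}

# CS events (tone/noise) of a schedule, with whether a shock starts exactly
# at their offset (a CS-US pairing).
schedule_cs_events <- function(schedule) {
  ev <- schedule$events
  cs <- ev[ev$kind %in% c("tone", "noise"), , drop = FALSE]
  if (nrow(cs)) {
    shock_on <- ev$onset[ev$kind == "shock"]
    cs$paired <- vapply(cs$onset + cs$duration, function(off) {
      any(abs(shock_on - off) < 1e-6)
    }, logical(1))
  }
  cs
}

#' Advance a subject's learning state through a session
#'
#' Applies the deterministic state updates implied by a schedule's events:
#' shocks increment the shock count and context fear, stimulus presentations
#' increment exposure counts, and CSs whose offset coincides with a shock
#' onset increment the pairing count for that CS kind.
#'
#' @param state A [subject_state()].
#' @param schedule An [event_schedule()].
#' @param params A [behavior_params()] (for `context_fear_increment`).
#' @return The updated `subject_state`.
#' @export
advance_state <- function(state, schedule, params = behavior_params()) {
  stopifnot(inherits(state, "subject_state"),
            inherits(schedule, "event_schedule"))
  ev <- schedule$events
  n_shock <- sum(ev$kind == "shock")
  cs <- schedule_cs_events(schedule)
  for (k in c("tone", "noise")) {
    state$exposures[[k]] <- state$exposures[[k]] + sum(cs$kind == k)
    if (nrow(cs)) {
      state$pairings[[k]] <- state$pairings[[k]] + sum(cs$kind == k & cs$paired)
    }
  }
  state$n_shocks <- state$n_shocks + n_shock
  state$context_fear <- clamp01(state$context_fear +
                                  params$context_fear_increment * n_shock)
  state
}

# Truncated-normal quantile transform: single uniform draw -> N(mean, sd)
# conditioned on being >= lb. Keeps the RNG draw count fixed (no rejection),
# which makes simulations comparable across parameter values under a shared
# seed.
qtruncnorm <- function(u, mean, sd, lb) {
  if (sd <= 0) return(pmax(lb, rep(mean, length(u))))
  p_lo <- stats::pnorm(lb, mean, sd)
  stats::qnorm(p_lo + u * (1 - p_lo), mean, sd)
}

#' Simulate one session of velocity, activity, and ground truth
#'
#' Synthesizes a session under a schedule: a lognormal AR(1) baseline speed
#' process; slot-wise freezing driven by context fear (outside CSs) or by
#' associative fear (during CSs); an onset dart at each tone/noise with
#' probability `clamp(sensitization_gain * n_shocks) *
#' habituation_decay^n_exposures`, using the running counts at the moment of
#' the event; an additional mid-CS dart with probability
#' `late_dart_prob_paired` in subjects with prior pairings of that CS; and a
#' reactivity burst at every shock. Every injected event is recorded in the
#' returned ground truth. All randomness is drawn in a schedule-determined
#' order, so a given `(schedule, params, state, seed)` reproduces the session
#' bit-exactly, and changing a probability parameter alone perturbs events
#' monotonically under a shared seed.
#'
#' @param schedule An [event_schedule()].
#' @param params A [behavior_params()].
#' @param state A [subject_state()] carrying the subject's history.
#' @param seed Integer seed (default `params$seed`). The session mutates the
#'   global RNG stream via `set.seed()`.
#' @param subject_id,session_id Identifiers stamped on the traces.
#' @return A list of class `sim_session`: `velocity` ([velocity_trace()]),
#'   `activity` ([activity_trace()]), `truth` (list with `dart_times`,
#'   `dart_magnitudes`, `freezing_bouts`, `shock_times`, `shock_magnitudes`,
#'   `fear_state_by_trial`), and `state` (the advanced [subject_state()]).
#' @export
simulate_session <- function(schedule, params = behavior_params(),
                             state = subject_state(), seed = params$seed,
                             subject_id = "s1", session_id = "ses1") {
  stopifnot(inherits(schedule, "event_schedule"),
            inherits(params, "behavior_params"),
            inherits(state, "subject_state"))
  set.seed(as.integer(seed))
  rate <- params$sampling_rate
  f_up <- as.integer(round(params$frame_rate / rate))
  n <- as.integer(floor(schedule$session_length * rate + .time_tol))
  tt <- (seq_len(n) - 1) / rate
  ev <- schedule$events
  cs <- schedule_cs_events(schedule)
  shocks <- ev[ev$kind == "shock", , drop = FALSE]
  # freezing is generated in slots aligned to the velocity sample grid (the
  # smallest whole number of samples spanning >= 1 s; 4 samples = 1.067 s at
  # 3.75 Hz), so bout edges coincide with both the velocity and the frame
  # grid and scored bouts can match ground truth exactly
  spb <- as.integer(ceiling(rate))          # samples per slot
  slot_dur <- spb / rate
  n_slots <- n %/% spb
  slot_start <- (seq_len(n_slots) - 1) * slot_dur

  ## -- fixed-order randomness ------------------------------------------------
  z_base <- stats::rnorm(n)
  n_cs <- nrow(cs)
  u_onset <- stats::runif(max(1, n_cs))[seq_len(n_cs)]
  u_mag <- stats::runif(max(1, n_cs))[seq_len(n_cs)]
  u_late <- stats::runif(max(1, n_cs))[seq_len(n_cs)]
  u_late_t <- stats::runif(max(1, n_cs))[seq_len(n_cs)]
  u_late_mag <- stats::runif(max(1, n_cs))[seq_len(n_cs)]
  n_sh <- nrow(shocks)
  u_shock <- stats::runif(max(1, n_sh))[seq_len(n_sh)]
  u_slot <- stats::runif(max(1, n_slots))[seq_len(n_slots)]
  u_vfreeze <- stats::runif(n)
  z_act <- stats::rnorm(n * f_up)
  u_actfreeze <- stats::runif(n * f_up)

  ## -- baseline locomotion ---------------------------------------------------
  s_log <- sqrt(log(1 + (params$baseline_sd / params$baseline_mean_speed)^2))
  phi <- params$baseline_ar_coeff
  x <- numeric(n)
  x[1] <- z_base[1] * s_log
  innov_sd <- s_log * sqrt(1 - phi^2)
  for (i in seq_len(n - 1L)) x[i + 1L] <- phi * x[i] + innov_sd * z_base[i + 1L]
  v <- pmin(params$baseline_clamp, params$baseline_mean_speed * exp(x))

  ## -- running histories -----------------------------------------------------
  shock_before <- function(t) {
    state$n_shocks + if (n_sh) sum(shocks$onset < t - 1e-9) else 0L
  }
  exposures_before <- function(kind, t) {
    state$exposures[[kind]] + sum(cs$kind == kind & cs$onset < t - 1e-9)
  }
  pairings_before <- function(kind, t) {
    state$pairings[[kind]] +
      if (n_cs) sum(cs$kind == kind & cs$paired &
                      (cs$onset + cs$duration) < t - 1e-9) else 0L
  }
  # context fear carried in from history plus shocks earlier in this session
  context_fear_at <- function(t) {
    extra <- if (n_sh) sum(shocks$onset < t - 1e-9) else 0L
    clamp01(state$context_fear + params$context_fear_increment * extra)
  }

  sample_at <- function(t) min(n, floor(t * rate + 1 - .time_tol) + 1L)
  first_sample_geq <- function(t) {
    i <- as.integer(ceiling(t * rate - .time_tol)) + 1L
    min(max(i, 1L), n)
  }

  ## -- darts at stimulus onsets and mid-CS -----------------------------------
  dart_times <- numeric(0)
  dart_mags <- numeric(0)
  dart_classes <- character(0)
  if (n_cs) {
    for (j in seq_len(n_cs)) {
      kind <- cs$kind[j]
      onset <- cs$onset[j]
      dur <- cs$duration[j]
      p_onset <- clamp01(params$sensitization_gain * shock_before(onset)) *
        params$habituation_decay^exposures_before(kind, onset)
      if (u_onset[j] < p_onset) {
        i0 <- first_sample_geq(onset)
        dart_times <- c(dart_times, tt[i0])
        dart_mags <- c(dart_mags,
                       qtruncnorm(u_mag[j], params$dart_peak_mean,
                                  params$dart_peak_sd,
                                  params$freeze_speed_ceiling))
        dart_classes <- c(dart_classes, "onset")
      }
      if (pairings_before(kind, onset) > 0 &&
          u_late[j] < params$late_dart_prob_paired && dur > 3) {
        t_late <- onset + dur / 2 + u_late_t[j] * (dur / 2 - 1.2)
        i1 <- first_sample_geq(t_late)
        dart_times <- c(dart_times, tt[i1])
        dart_mags <- c(dart_mags,
                       qtruncnorm(u_late_mag[j],
                                  params$late_dart_peak_frac * params$dart_peak_mean,
                                  params$dart_peak_sd,
                                  params$freeze_speed_ceiling))
        dart_classes <- c(dart_classes, "late")
      }
    }
  }

  ## -- shock reactivity bursts -----------------------------------------------
  shock_times <- numeric(0)
  shock_mags <- numeric(0)
  if (n_sh) {
    shock_times <- tt[vapply(shocks$onset, first_sample_geq, integer(1))]
    shock_mags <- qtruncnorm(u_shock, params$shock_peak_mean,
                             params$shock_peak_sd,
                             params$freeze_speed_ceiling)
  }

  ## -- freezing slots --------------------------------------------------------
  fear <- vapply(slot_start, context_fear_at, 1)
  if (n_cs) {
    for (j in seq_len(n_cs)) {
      # a slot takes the CS fear level if it overlaps the CS window at all,
      # so forced freezing covers the CS completely even though slot edges
      # sit on the velocity grid rather than on event onsets
      idx <- which(slot_start < cs$onset[j] + cs$duration[j] - .time_tol &
                     slot_start + slot_dur > cs$onset[j] + .time_tol)
      if (length(idx)) {
        assoc <- clamp01(pairings_before(cs$kind[j], cs$onset[j]) *
                           params$assoc_increment)
        fear[idx] <- clamp01(assoc + 0.5 * fear[idx])
      }
    }
  }
  p_freeze <- clamp01(fear * params$fear_freeze_slope)
  frozen <- u_slot < p_freeze
  # no freezing in slots that contain an injected burst or a shock window
  excl_times <- c(dart_times, if (n_sh) as.vector(outer(shocks$onset, c(0, 0.5, 1, 1.5), `+`)))
  if (length(excl_times)) {
    excl_slots <- unique(pmin(n_slots, floor(excl_times / slot_dur) + 1L))
    frozen[excl_slots[excl_slots >= 1L]] <- FALSE
  }
  r <- rle(frozen)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  keep <- r$values
  bouts <- data.frame(start = slot_start[starts_i[keep]],
                      end = slot_start[starts_i[keep]] + r$lengths[keep] * slot_dur)
  bouts$end <- pmin(bouts$end, schedule$session_length)

  # membership of times in the (disjoint, ordered) bouts
  in_bouts <- function(times) {
    if (!nrow(bouts)) return(rep(FALSE, length(times)))
    pos <- findInterval(times + .time_tol, bouts$start)
    pos >= 1L & times < bouts$end[pmax(pos, 1L)] - .time_tol
  }

  ## -- assemble the velocity trace -------------------------------------------
  in_bout <- in_bouts(tt)
  v[in_bout] <- u_vfreeze[in_bout] * 0.8 * params$freeze_speed_ceiling

  place_burst <- function(v, t, mag, shoulder_frac) {
    i <- sample_at(t)
    v[i] <- mag
    if (shoulder_frac > 0) {
      if (i > 1L) v[i - 1L] <- max(v[i - 1L], shoulder_frac * mag)
      if (i < n) v[i + 1L] <- max(v[i + 1L], shoulder_frac * mag)
    }
    v
  }
  dart_shoulder <- if (params$dart_duration * rate >= 2) 0.45 else 0
  for (d in seq_along(dart_times)) {
    v <- place_burst(v, dart_times[d], dart_mags[d], dart_shoulder)
  }
  for (s in seq_along(shock_times)) {
    i <- sample_at(shock_times[s])
    v[i] <- shock_mags[s]
    if (i + 1L <= n) v[i + 1L] <- max(v[i + 1L], 0.5 * shock_mags[s])
    if (i + 2L <= n) v[i + 2L] <- max(v[i + 2L], 0.25 * shock_mags[s])
  }

  ## -- activity as a monotone noisy transform of speed -----------------------
  v_f <- rep(v, each = f_up)
  act <- params$activity_scale * v_f * exp(params$activity_noise_sd * z_act)
  t_f <- (seq_along(act) - 1) / params$frame_rate
  in_bout_f <- in_bouts(t_f)
  act[in_bout_f] <- u_actfreeze[in_bout_f] * 0.8 * params$activity_freeze_threshold

  ## -- ground truth and state ------------------------------------------------
  ord <- order(dart_times)
  trial_ids <- if (nrow(ev)) sort(unique(ev$trial_index)) else integer()
  fear_by_trial <- do.call(rbind, lapply(trial_ids, function(k) {
    tr_ev <- ev[ev$trial_index == k, , drop = FALSE]
    t_on <- min(tr_ev$onset)
    first_cs <- cs[cs$trial_index == k, , drop = FALSE]
    assoc <- if (nrow(first_cs)) {
      clamp01(pairings_before(first_cs$kind[1], first_cs$onset[1]) *
                params$assoc_increment)
    } else 0
    data.frame(trial_index = k, context_fear = context_fear_at(t_on),
               assoc_fear = assoc)
  }))
  truth <- list(
    dart_times = dart_times[ord],
    dart_magnitudes = dart_mags[ord],
    dart_classes = dart_classes[ord],
    freezing_bouts = bouts,
    shock_times = shock_times,
    shock_magnitudes = as.numeric(shock_mags),
    fear_state_by_trial = fear_by_trial)

  out <- list(
    velocity = velocity_trace(v, rate, subject_id, session_id),
    activity = activity_trace(act, params$frame_rate, subject_id, session_id),
    truth = truth,
    state = advance_state(state, schedule, params))
  class(out) <- "sim_session"
  out
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("<sim session> %s/%s: %d velocity samples, %d ground-truth darts, %d freezing bouts\n",
              x$velocity$subject_id, x$velocity$session_id,
              length(x$velocity$samples), length(x$truth$dart_times),
              nrow(x$truth$freezing_bouts)))
  invisible(x)
}

derive_seed <- function(seed, i, j = 0L) {
  as.integer((as.numeric(seed) + 1009 * i + 9973 * j) %% 2147483647)
}

#' Simulate one subject through a multi-day design
#'
#' Threads the subject's learning state across the days of a design
#' (habituation, training, test). Days whose phase is not in
#' `synthesize_phases` only advance the state (the state update is
#' deterministic), which makes test-day-only studies cheap.
#'
#' @param design A list of per-day schedules from [make_design()].
#' @param params A [behavior_params()].
#' @param subject_id Identifier.
#' @param seed Integer seed; each day derives its own sub-seed.
#' @param synthesize_phases Phases for which traces are generated (default
#'   all of `"habituation"`, `"training"`, `"test"`).
#' @return List with `sessions` (named list of `sim_session`, synthesized
#'   days only) and `state` (final [subject_state()]).
#' @export
simulate_subject <- function(design, params = behavior_params(),
                             subject_id = "s1", seed = params$seed,
                             synthesize_phases = c("habituation", "training", "test")) {
  state <- subject_state()
  sessions <- list()
  for (d in seq_along(design)) {
    sched <- design[[d]]
    phase <- attr(sched, "phase") %||% "training"
    if (phase %in% synthesize_phases) {
      ses <- simulate_session(sched, params, state,
                              seed = derive_seed(seed, d),
                              subject_id = subject_id,
                              session_id = names(design)[d] %||% paste0("day", d))
      sessions[[names(design)[d] %||% paste0("day", d)]] <- ses
      state <- ses$state
    } else {
      state <- advance_state(state, sched, params)
    }
  }
  list(sessions = sessions, state = state)
}

#' Simulate a cohort for one experimental group
#'
#' @param experiment,group Design cell, as in [make_design()].
#' @param n_per_group Number of subjects (default 8, the standard powered
#'   group size for these designs).
#' @param params A [behavior_params()].
#' @param seed Integer seed; subjects and days derive sub-seeds.
#' @param iti Passed to [make_design()]; each subject gets its own ITI draw.
#' @param synthesize_phases See [simulate_subject()].
#' @return A list of per-subject results (see [simulate_subject()]), named by
#'   subject id `<group>_<k>`.
#' @export
simulate_cohort <- function(experiment, group, n_per_group = 8L,
                            params = behavior_params(), seed = params$seed,
                            iti = c(150, 210),
                            synthesize_phases = c("habituation", "training", "test")) {
  out <- lapply(seq_len(n_per_group), function(k) {
    sid <- sprintf("%s_%02d", normalize_group(group), k)
    design <- make_design(experiment, group, iti = iti,
                          seed = derive_seed(seed, k, 777L))
    subj <- simulate_subject(design, params, subject_id = sid,
                             seed = derive_seed(seed, k),
                             synthesize_phases = synthesize_phases)
    subj$design <- design
    subj
  })
  names(out) <- sprintf("%s_%02d", normalize_group(group), seq_len(n_per_group))
  out
}
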