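#' Sample fetal movement events
#'
#' Draws the fetal event process used by [simulate_trial()].  Events arrive
#' as a Neyman-Scott cluster process: cluster centres follow a Poisson
#' process of rate `event_rate / event_cluster_factor` and each centre
#' spawns `1 + Poisson(event_cluster_factor - 1)` events spread forward in
#' time with exponential gaps (mean 3 s), so the marginal mean rate equals
#' `event_rate` while events cluster, as fetal movements tend to.  Each
#' event carries a duration (uniform 0.3--3 s), an amplitude jitter, a
#' perceptibility rank (the quantile of duration x amplitude), a carrier frequency
#' (uniform in `event_band`), and a footprint of 1..`event_footprint`
#' abdominal sensors; the chest reference is never in a footprint.
#'
#' @param config An [sim_config()] object.
#' @param seed Integer seed; the draw is reproducible.
#' @return A data.frame with one row per event: `onset`, `duration`,
#'   `freq`, `phase`, `amp_jitter`, and a list-column `sensors` of affected
#'   abdominal sensor indices.
#' @export
sample_fetal_events <- function(config, seed) {
  validate_sim_config(config)
  set.seed(seed)
  dur <- config$trial_duration
  k <- config$event_cluster_factor
  centre_rate <- config$event_rate / k
  n_centres <- rpois(1L, centre_rate * dur)
  onsets <- numeric(0)
  if (n_centres > 0) {
    centres <- runif(n_centres, 0, dur)
    for (cc in centres) {
      n_spawn <- 1L + rpois(1L, k - 1)
      gaps <- c(0, cumsum(rexp(n_spawn - 1L, rate = 1 / 3)))[seq_len(n_spawn)]
      onsets <- c(onsets, cc + gaps)
    }
  }
  onsets <- sort(onsets[onsets < dur])
  n_ev <- length(onsets)
  ev <- data.frame(
    onset = onsets,
    duration = runif(n_ev, 0.3, 3),
    freq = runif(n_ev, config$event_band[1], config$event_band[2]),
    phase = runif(n_ev, 0, 2 * pi),
    amp_jitter = runif(n_ev, 0.5, 1.5)
  )
  # perceptibility rank in [0, 1]: the quantile of duration x amplitude,
  # used to bias maternal perception toward long, strong movements
  ev$percept_score <- strength_quantile(ev$duration * ev$amp_jitter)
  ev$sensors <- lapply(seq_len(n_ev), function(i) {
    size <- sample.int(config$event_footprint, 1L)
    sort(sample.int(config$n_abdominal, size))
  })
  ev
}

# CDF of the product d * a with d ~ U(0.3, 3) and a ~ U(0.5, 1.5),
# evaluated by quadrature over d.  Monotone in the product, so it ranks
# events by "strength" on a uniform [0, 1] scale.
strength_quantile <- function(w) {
  if (length(w) == 0L) return(numeric(0))
  dgrid <- seq(0.3, 3, length.out = 400L)
  vapply(w, function(t)
    mean(pmin(pmax((t / dgrid - 0.5), 0), 1)), 0)
}

# Truncated-normal reaction delays on [0, 3.5] s via inverse-CDF sampling,
# so the true onset stays inside the press-derived event interval.
sample_reaction_delays <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  if (sd <= 0) return(rep(min(max(mean, 0), 3.5), n))
  p_lo <- stats::pnorm((0 - mean) / sd)
  p_hi <- stats::pnorm((3.5 - mean) / sd)
  u <- runif(n, p_lo, p_hi)
  mean + sd * stats::qnorm(u)
}

# Shared torso-motion bursts: smooth Hann-windowed oscillations below 2 Hz
# about random global axes.  Returns n x 3 matrices for angular rate and
# linear acceleration (same burst envelope, independent directions).
maternal_motion <- function(config, n) {
  fs <- config$fs
  dur <- config$trial_duration
  omega <- matrix(0, n, 3)
  lin <- matrix(0, n, 3)
  n_bursts <- rpois(1L, config$maternal_burst_rate * dur)
  if (n_bursts > 0) {
    for (b in seq_len(n_bursts)) {
      onset <- runif(1, 0, dur)
      blen <- runif(1, 1, 3)
      freq <- runif(1, 0.3, 2)
      amp <- config$maternal_amplitude * runif(1, 0.5, 1.5)
      ax_g <- random_unit_vector()
      ax_a <- random_unit_vector()
      i0 <- floor(onset * fs) + 1L
      i1 <- min(n, floor((onset + blen) * fs))
      if (i1 < i0) next
      t_rel <- (seq.int(i0, i1) - 1) / fs - onset
      env <- 0.5 * (1 - cos(2 * pi * t_rel / blen))
      w <- amp * env * sin(2 * pi * freq * t_rel)
      omega[i0:i1, ] <- omega[i0:i1, ] + outer(w, ax_g)
      lin[i0:i1, ] <- lin[i0:i1, ] + outer(w, ax_a)
    }
  }
  list(omega = omega, lin = lin)
}

# Very-low-frequency baseline drift per channel: a sum of three slow
# sinusoids with random frequency (0.02-0.3 Hz), phase, and amplitude.
drift_channel <- function(n, fs, scale) {
  t <- (seq_len(n) - 1) / fs
  out <- numeric(n)
  for (j in 1:3) {
    f <- runif(1, 0.02, 0.3)
    a <- scale * runif(1, 0.3, 1)
    out <- out + a * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
  }
  out
}

gravity_vec <- function() c(9.81, 0, 0)

#' Simulate one multi-sensor trial with ground truth
#'
#' Generates a synchronized recording of `n_abdominal + 1` tri-axial IMUs
#' (acceleration and angular rate) at `config$fs` Hz.  Maternal torso
#' motion is a single shared global angular-velocity / linear-acceleration
#' signal rotated into each sensor's local frame by its mounting rotation;
#' gravity appears as a quasi-constant accelerometer component; each fetal
#' event adds an exponentially damped band-limited sinusoidal burst to the
#' acceleration and angular rate of its footprint sensors only.  The chest
#' reference (last sensor) never receives fetal bursts.  Maternal
#' perception marks the strongest `p_perceive` fraction of events (ranked
#' by duration x amplitude, since mothers feel the pronounced movements)
#' with a button press, delayed by a truncated-normal reaction time.
#'
#' Independent random-number substreams are used for mounting, maternal
#' motion, drift, noise, events, and perception, so disabling fetal events
#' leaves every sample outside event supports bit-identical.
#'
#' @param config An [sim_config()] object.
#' @param seed Integer master seed for the trial.
#' @return A list with components `trial` (class `fm_trial`: arrays
#'   `acc` and `gyr` of dim `[n_samples, 3, n_sensors]`, `fs`,
#'   `press_times`, `sensor_roles`, `mounting`) and `truth` (class
#'   `fm_ground_truth`: event onsets, durations, footprints, perception
#'   indicators, delays, press times).
#' @examples
#' sim <- simulate_trial(sim_config(trial_duration = 20), seed = 1)
#' dim(sim$trial$acc)
#' @export
simulate_trial <- function(config, seed) {
  validate_sim_config(config)
  if (config$trial_duration < 0.5)
    stop("trial_duration too short: must contain at least one 0.5 s analysis window")
  fs <- config$fs
  n <- round(fs * config$trial_duration)
  n_sensors <- config$n_abdominal + 1L
  ref <- n_sensors

  # mounting rotations (substream 1; shared with simulate_calibration)
  if (is.null(config$mounting_rotations)) {
    set.seed(derive_seed(seed, 1L))
    mounting <- replicate(n_sensors, random_mounting_rotation(), simplify = FALSE)
  } else {
    mounting <- config$mounting_rotations
  }

  # shared maternal motion (substream 2)
  set.seed(derive_seed(seed, 2L))
  mat <- maternal_motion(config, n)

  acc <- array(0, dim = c(n, 3L, n_sensors))
  gyr <- array(0, dim = c(n, 3L, n_sensors))
  g <- gravity_vec()
  for (s in seq_len(n_sensors)) {
    Mt <- t(mounting[[s]])
    acc[, , s] <- sweep(mat$lin %*% t(Mt), 2L, as.numeric(Mt %*% g), "+")
    gyr[, , s] <- mat$omega %*% t(Mt)
  }

  # drift (substream 3)
  if (config$drift_scale > 0) {
    set.seed(derive_seed(seed, 3L))
    for (s in seq_len(n_sensors)) for (a in 1:3) {
      acc[, a, s] <- acc[, a, s] + drift_channel(n, fs, config$drift_scale)
      gyr[, a, s] <- gyr[, a, s] + drift_channel(n, fs, config$drift_scale * 0.1)
    }
  }

  # measurement noise (substream 4)
  if (config$noise_sd_acc > 0 || config$noise_sd_gyr > 0) {
    set.seed(derive_seed(seed, 4L))
    acc <- acc + array(rnorm(length(acc), sd = config$noise_sd_acc), dim = dim(acc))
    gyr <- gyr + array(rnorm(length(gyr), sd = config$noise_sd_gyr), dim = dim(gyr))
  }

  # fetal events (substream 5), localized to their footprint sensors
  events <- sample_fetal_events(config, derive_seed(seed, 5L))
  n_ev <- nrow(events)
  if (n_ev > 0) {
    for (e in seq_len(n_ev)) {
      i0 <- floor(events$onset[e] * fs) + 1L
      i1 <- min(n, floor((events$onset[e] + events$duration[e]) * fs))
      if (i1 < i0) next
      t_rel <- (seq.int(i0, i1) - 1) / fs - events$onset[e]
      env <- exp(-3 * t_rel / events$duration[e])
      w <- env * sin(2 * pi * events$freq[e] * t_rel + events$phase[e])
      for (s in events$sensors[[e]]) {
        acc[i0:i1, , s] <- acc[i0:i1, , s] +
          config$event_amplitude_acc * events$amp_jitter[e] * outer(w, random_unit_vector())
        gyr[i0:i1, , s] <- gyr[i0:i1, , s] +
          config$event_amplitude_gyr * events$amp_jitter[e] * outer(w, random_unit_vector())
      }
    }
  }

  # maternal perception (substream 6): the strongest (longest, largest)
  # movements are the ones the mother feels, so an event is perceived when
  # its strength quantile lies in the top p_perceive fraction; the marginal
  # perception rate is p_perceive by construction
  set.seed(derive_seed(seed, 6L))
  perceived <- if (n_ev > 0) events$percept_score >= 1 - config$p_perceive else logical(0)
  delays <- rep(NA_real_, n_ev)
  delays[perceived] <- sample_reaction_delays(
    sum(perceived), config$reaction_delay_mean, config$reaction_delay_sd)
  press_times <- events$onset[perceived] + delays[perceived]
  keep <- press_times <= config$trial_duration
  press_times <- sort(press_times[keep])

  trial <- structure(list(
    acc = acc, gyr = gyr, fs = fs,
    duration = config$trial_duration,
    press_times = press_times,
    sensor_roles = list(abdominal = seq_len(config$n_abdominal), reference = ref),
    mounting = mounting
  ), class = "fm_trial")
  truth <- structure(list(
    event_onsets = events$onset,
    event_durations = events$duration,
    event_sensors = events$sensors,
    perceived = perceived,
    reaction_delays = delays,
    press_times = press_times
  ), class = "fm_ground_truth")
  list(trial = trial, truth = truth)
}

#' @export
print.fm_trial <- function(x, ...) {
  cat(sprintf("fm_trial: %d sensors x 3 axes x %d samples @ %g Hz (%.1f s), %d presses\n",
              dim(x$acc)[3], dim(x$acc)[1], x$fs, x$duration, length(x$press_times)))
  invisible(x)
}

#' Simulate a calibration recording
#'
#' Produces the functional-alignment calibration segment: quiet standing
#' (8 s) followed by three hip-hinge repetitions (lean forward about the
#' frontal axis, hold, return).  The lean is faster than the return, so
#' peak angular velocity identifies the forward-lean direction.  Uses the
#' same mounting rotations as [simulate_trial()] called with the same seed,
#' so a trial and its calibration describe one mounting session.
#'
#' @param config An [sim_config()] object.
#' @param seed Integer seed (same seed as the companion trial).
#' @return An object of class `fm_calibration`: arrays `acc`, `gyr`
#'   (`[n_samples, 3, n_sensors]`), `fs`, `phases` (data.frame with
#'   columns `phase`, `start_sample`, `end_sample` for `"static"` and
#'   `"hinge1"`..`"hinge3"`), and `mounting`.
#' @export
simulate_calibration <- function(config, seed) {
  validate_sim_config(config)
  fs <- config$fs
  n_sensors <- config$n_abdominal + 1L

  if (is.null(config$mounting_rotations)) {
    set.seed(derive_seed(seed, 1L))
    mounting <- replicate(n_sensors, random_mounting_rotation(), simplify = FALSE)
  } else {
    mounting <- config$mounting_rotations
  }

  set.seed(derive_seed(seed, 7L))
  static_len <- 8
  lean_len <- 1.2; hold_len <- 0.5; return_len <- 2.0; pause_len <- 0.8
  theta_max <- 30 * pi / 180

  seg_omega <- numeric(0)          # angular velocity about the frontal axis
  phases <- data.frame(phase = character(0), start_sample = integer(0),
                       end_sample = integer(0))
  add_samples <- function(len) round(len * fs)

  n_static <- add_samples(static_len)
  seg_omega <- c(seg_omega, numeric(n_static))
  phases <- rbind(phases, data.frame(phase = "static", start_sample = 1L,
                                     end_sample = n_static))
  cursor <- n_static
  for (h in 1:3) {
    jit <- runif(1, 0.9, 1.1)
    n_lean <- add_samples(lean_len); n_hold <- add_samples(hold_len)
    n_ret <- add_samples(return_len); n_pause <- add_samples(pause_len)
    t_l <- (seq_len(n_lean) - 0.5) / fs
    t_r <- (seq_len(n_ret) - 0.5) / fs
    hann_l <- 0.5 * (1 - cos(2 * pi * t_l / lean_len))
    hann_r <- 0.5 * (1 - cos(2 * pi * t_r / return_len))
    amp_l <- jit * theta_max / (0.5 * lean_len)   # integral of Hann bump = len/2
    amp_r <- jit * theta_max / (0.5 * return_len)
    w <- c(amp_l * hann_l, numeric(n_hold), -amp_r * hann_r)
    seg_omega <- c(seg_omega, w, numeric(n_pause))
    phases <- rbind(phases, data.frame(
      phase = paste0("hinge", h),
      start_sample = cursor + 1L,
      end_sample = cursor + n_lean + n_hold + n_ret))
    cursor <- cursor + n_lean + n_hold + n_ret + n_pause
  }
  n <- length(seg_omega)
  theta <- cumsum(seg_omega) / fs
  omega_global <- outer(seg_omega, c(0, 1, 0))    # rotation about global frontal axis

  g <- gravity_vec()
  acc <- array(0, dim = c(n, 3L, n_sensors))
  gyr <- array(0, dim = c(n, 3L, n_sensors))
  # torso-frame gravity while leaning by theta about the frontal (y) axis
  grav_torso <- cbind(g[1] * cos(theta), 0, g[1] * sin(theta))
  for (s in seq_len(n_sensors)) {
    Mt <- t(mounting[[s]])
    acc[, , s] <- grav_torso %*% t(Mt) +
      matrix(rnorm(n * 3L, sd = config$noise_sd_acc), n, 3L)
    gyr[, , s] <- omega_global %*% t(Mt) +
      matrix(rnorm(n * 3L, sd = config$noise_sd_gyr), n, 3L)
  }

  structure(list(acc = acc, gyr = gyr, fs = fs, phases = phases,
                 mounting = mounting), class = "fm_calibration")
}

#' Simulate a cohort of trials
#'
#' Generates `n_trials` independent trials, each with its ground truth and
#' a calibration recording sharing the trial's mounting rotations.
#' Per-trial seeds are derived deterministically from the master seed, so
#' the same call reproduces the cohort bit-for-bit.
#'
#' @param n_trials Number of trials (the study default is 49).
#' @param config An [sim_config()] object.
#' @param seed Integer master seed.
#' @return A list of class `fm_cohort`; each element has `trial`, `truth`,
#'   and `calibration`.
#' @export
make_cohort <- function(n_trials, config = sim_config(), seed = 1L) {
  stopifnot(n_trials >= 1)
  cohort <- lapply(seq_len(n_trials), function(i) {
    trial_seed <- derive_seed(seed, 1000L + i)
    sim <- simulate_trial(config, trial_seed)
    calib <- simulate_calibration(config, trial_seed)
    list(trial = sim$trial, truth = sim$truth, calibration = calib)
  })
  names(cohort) <- sprintf("trial%02d", seq_len(n_trials))
  structure(cohort, class = "fm_cohort", seed = seed)
}
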