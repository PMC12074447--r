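#' Simulation configuration
#'
#' Parameters of the synthetic multi-sensor recording generator.  The
#' generator emulates five tri-axial inertial measurement units (IMUs) --
#' four abdominal plus one chest reference -- sampled synchronously at
#' `fs` Hz.  All sensors share a rigid-body maternal torso motion (rotated
#' into each sensor's local frame by its mounting rotation) plus gravity;
#' fetal events add short band-limited bursts to the abdominal sensors in
#' their footprint only; maternal perception converts a fraction
#' `p_perceive` of true events into delayed button presses.
#'
#' @param fs Sampling rate in Hz.
#' @param trial_duration Trial length in seconds.
#' @param n_abdominal Number of abdominal sensors (the chest reference is
#'   always added as one extra sensor).
#' @param event_rate Mean fetal event rate, events per second.
#' @param event_cluster_factor Burstiness multiplier (>= 1).  Events are
#'   generated as a Neyman-Scott cluster process: cluster centres arrive at
#'   rate `event_rate / event_cluster_factor` and each spawns on average
#'   `event_cluster_factor` events, so the mean rate is preserved while
#'   events cluster in time.  `1` gives a plain Poisson process.
#' @param event_amplitude_acc,event_amplitude_gyr Scale of the fetal burst
#'   added to acceleration (m/s^2) and angular rate (rad/s).
#' @param event_band Two-element numeric, the frequency band (Hz) in which
#'   fetal burst carrier frequencies are drawn.  Must lie inside
#'   (0, fs/2).
#' @param event_footprint Maximum number of abdominal sensors receiving each
#'   burst (each event affects 1..event_footprint sensors, never the chest
#'   reference).
#' @param maternal_burst_rate Rate (per second) of shared low-frequency
#'   torso-motion bursts.
#' @param maternal_amplitude Scale of the shared torso motion (applied as
#'   rad/s to angular rate and m/s^2 to linear acceleration).
#' @param p_perceive Fraction of true fetal events producing a button
#'   press.  Perception is biased toward pronounced movements: the events
#'   in the top `p_perceive` fraction by strength (duration x amplitude
#'   quantile) are the perceived ones, so the marginal perception rate is
#'   `p_perceive` while weak, short movements go unreported.
#' @param reaction_delay_mean,reaction_delay_sd Mean and standard deviation
#'   (seconds) of the press reaction delay; the delay distribution is a
#'   normal truncated to [0, 3.5] s so that the true onset always falls
#'   inside the press-derived event interval.
#' @param noise_sd_acc,noise_sd_gyr White measurement-noise standard
#'   deviations (m/s^2, rad/s).
#' @param drift_scale Amplitude of very-low-frequency baseline drift
#'   (removed downstream by the bandpass filter).
#' @param mounting_rotations Optional list of per-sensor 3x3 orthonormal
#'   mounting rotation matrices (length `n_abdominal + 1`).  `NULL` (the
#'   default) draws small random mounting rotations per trial.
#'
#' @return An object of class `fm_sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(trial_duration = 60)
#' cfg$fs
#' @export
sim_config <- function(fs = 128,
                       trial_duration = 300,
                       n_abdominal = 4,
                       event_rate = 0.055,
                       event_cluster_factor = 2,
                       event_amplitude_acc = 0.6,
                       event_amplitude_gyr = 0.3,
                       event_band = c(1, 10),
                       event_footprint = 2,
                       maternal_burst_rate = 0.1,
                       maternal_amplitude = 0.5,
                       p_perceive = 0.4,
                       reaction_delay_mean = 0.6,
                       reaction_delay_sd = 0.3,
                       noise_sd_acc = 0.05,
                       noise_sd_gyr = 0.02,
                       drift_scale = 0.1,
                       mounting_rotations = NULL) {
  cfg <- list(
    fs = fs, trial_duration = trial_duration, n_abdominal = n_abdominal,
    event_rate = event_rate, event_cluster_factor = event_cluster_factor,
    event_amplitude_acc = event_amplitude_acc,
    event_amplitude_gyr = event_amplitude_gyr,
    event_band = event_band, event_footprint = event_footprint,
    maternal_burst_rate = maternal_burst_rate,
    maternal_amplitude = maternal_amplitude,
    p_perceive = p_perceive,
    reaction_delay_mean = reaction_delay_mean,
    reaction_delay_sd = reaction_delay_sd,
    noise_sd_acc = noise_sd_acc, noise_sd_gyr = noise_sd_gyr,
    drift_scale = drift_scale,
    mounting_rotations = mounting_rotations
  )
  class(cfg) <- "fm_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "fm_sim_config"))
  if (!(is.numeric(cfg$fs) && length(cfg$fs) == 1L && cfg$fs > 0))
    stop("fs must be a positive scalar")
  if (!(cfg$trial_duration > 0))
    stop("trial_duration must be positive")
  if (cfg$p_perceive < 0 || cfg$p_perceive > 1)
    stop("p_perceive must lie in [0, 1]")
  if (length(cfg$event_band) != 2L || cfg$event_band[1] <= 0 ||
      cfg$event_band[2] <= cfg$event_band[1] ||
      cfg$event_band[2] >= cfg$fs / 2)
    stop("event_band must satisfy 0 < low < high < fs/2 (Nyquist)")
  if (cfg$event_cluster_factor < 1)
    stop("event_cluster_factor must be >= 1")
  if (cfg$event_footprint < 1 || cfg$event_footprint > cfg$n_abdominal)
    stop("event_footprint must be in 1..n_abdominal")
  if (!is.null(cfg$mounting_rotations)) {
    n_sensors <- cfg$n_abdominal + 1L
    if (length(cfg$mounting_rotations) != n_sensors)
      stop("mounting_rotations must have one matrix per sensor (", n_sensors, ")")
    for (R in cfg$mounting_rotations) {
      if (!is.matrix(R) || any(dim(R) != c(3L, 3L)))
        stop("each mounting rotation must be a 3x3 matrix")
      if (max(abs(crossprod(R) - diag(3))) > 1e-9)
        stop("each mounting rotation must be orthonormal (R'R = I within 1e-9)")
    }
  }
  invisible(cfg)
}

#' @export
print.fm_sim_config <- function(x, ...) {
  cat("Simulation configuration (fm_sim_config)\n")
  cat(sprintf("  %d+1 sensors, %.0f Hz, %.0f s trials\n",
              x$n_abdominal, x$fs, x$trial_duration))
  cat(sprintf("  fetal events: rate %.3g/s, cluster factor %.2g, band %g-%g Hz\n",
              x$event_rate, x$event_cluster_factor,
              x$event_band[1], x$event_band[2]))
  cat(sprintf("  perception: p = %.2f, delay %.2f +/- %.2f s\n",
              x$p_perceive, x$reaction_delay_mean, x$reaction_delay_sd))
  invisible(x)
}

# Rotation about a unit axis by angle (radians), Rodrigues form.
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Uniform random unit vector.
random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Random small mounting rotation: random axis, angle uniform in [0, max_angle].
random_mounting_rotation <- function(max_angle = 20 * pi / 180) {
  rotation_about_axis(random_unit_vector(), runif(1, 0, max_angle))
}

# Deterministic per-substream seed derivation from a master seed.
# Simple splitmix-style integer hash, kept inside the 32-bit range R accepts.
derive_seed <- function(seed, stream) {
  x <- (as.double(seed) * 2654435761 + as.double(stream) * 40503 + 97) %% 2147483647
  as.integer(x)
}
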