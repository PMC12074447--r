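#' Bandpass filter specification
#'
#' @param low_cut,high_cut Passband edges in Hz (defaults 1 and 20).
#' @param order Butterworth order of the underlying one-pass design (the
#'   forward-backward application doubles the effective order).
#' @param design Filter family; only `"butter"` is implemented.
#' @return An object of class `fm_filter_spec`.
#' @export
filter_spec <- function(low_cut = 1, high_cut = 20, order = 4L,
                        design = "butter") {
  if (!(low_cut > 0 && high_cut > low_cut))
    stop("need 0 < low_cut < high_cut")
  if (design != "butter") stop("only the Butterworth design is implemented")
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 order = as.integer(order), design = design),
            class = "fm_filter_spec")
}

butter_coefs <- function(spec, fs) {
  if (spec$high_cut >= fs / 2)
    stop("high_cut must be below the Nyquist frequency fs/2")
  bf <- signal::butter(spec$order,
                       c(spec$low_cut, spec$high_cut) / (fs / 2),
                       type = "pass")
  list(b = bf$b, a = bf$a)
}

#' Zero-phase bandpass filtering
#'
#' Applies the Butterworth bandpass filter forward and backward
#' (zero net phase, squared magnitude response).  Edges are handled by
#' odd-reflection padding of three times the filter's coefficient length,
#' which suppresses start-up transients at the trial boundaries; the
#' output has the same length as the input.
#'
#' @param x Numeric vector, or a matrix/array filtered column-wise along
#'   the first dimension.
#' @param fs Sampling rate in Hz.
#' @param spec An [filter_spec()] (default 1--20 Hz, order 4).
#' @return Filtered signal, same shape as `x`.
#' @examples
#' x <- sin(2 * pi * 10 * (0:1023) / 128)
#' y <- bandpass_zero_phase(x, 128)
#' @export
bandpass_zero_phase <- function(x, fs, spec = filter_spec()) {
  co <- butter_coefs(spec, fs)
  pad <- 3L * max(length(co$a), length(co$b))
  if (is.null(dim(x))) {
    return(filtfilt_padded(x, co$b, co$a, pad))
  }
  dims <- dim(x)
  m <- matrix(x, nrow = dims[1])
  for (j in seq_len(ncol(m))) m[, j] <- filtfilt_padded(m[, j], co$b, co$a, pad)
  array(m, dim = dims, dimnames = dimnames(x))
}

# Forward-backward IIR filtering with odd-reflection padding (the padding
# mirrors the signal about its end points so the extension is continuous in
# value, which keeps the filter transient off the retained samples).
filtfilt_padded <- function(x, b, a, pad) {
  n <- length(x)
  if (n <= pad)
    stop(sprintf("signal too short for zero-phase filtering: need more than %d samples, got %d",
                 pad, n))
  pre <- 2 * x[1] - x[seq(pad + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - pad)]
  ext <- c(pre, x, post)
  # steady-state initial conditions (as if the first/last value had been
  # applied forever) remove the filter warm-up transient
  hdc <- sum(b) / sum(a)
  m <- max(length(a), length(b)) - 1L
  run <- function(v) {
    signal::filter(b, a, v,
                   init.x = rep(v[1], m), init.y = rep(v[1] * hdc, m))
  }
  y <- run(ext)
  y <- rev(run(rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Magnitude response of the zero-phase filter
#'
#' Returns |H(f)|^2, the effective amplitude gain of
#' [bandpass_zero_phase()] at the requested frequencies (the squared
#' one-pass response, since the filter is applied forward and backward).
#'
#' @param freqs Frequencies in Hz.
#' @param fs Sampling rate in Hz.
#' @param spec An [filter_spec()].
#' @return Numeric vector of amplitude gains.
#' @export
bandpass_response <- function(freqs, fs, spec = filter_spec()) {
  co <- butter_coefs(spec, fs)
  w <- 2 * pi * freqs / fs
  z <- exp(-1i * w)
  h <- sapply(seq_along(z), function(i) {
    num <- sum(co$b * z[i]^(0:(length(co$b) - 1)))
    den <- sum(co$a * z[i]^(0:(length(co$a) - 1)))
    num / den
  })
  Mod(h)^2
}

#' Estimate functional alignment transforms from a calibration recording
#'
#' Implements the functional alignment of sensor axes to anatomical axes:
#' during quiet standing the accelerometer mean identifies the gravity
#' direction (anatomical x); the dominant rotation axis of the hip-hinge
#' gyroscope data, orthogonalized against gravity, identifies the frontal
#' axis (anatomical y, sign chosen so the faster forward-lean rotation is
#' positive); their cross product gives the sagittal axis (anatomical z).
#' Raw (unfiltered) calibration data must be used: the bandpass filter
#' would remove the gravity component the method depends on.
#'
#' @param calib An `fm_calibration` recording.
#' @return A list of class `fm_alignment`: one 3x3 orthonormal rotation
#'   matrix per sensor whose columns are the gravity, frontal, and sagittal
#'   directions expressed in the sensor frame.  Anatomical-frame
#'   coordinates of a sensor-frame row-vector signal `v` are `v %*% R`.
#' @export
estimate_alignment <- function(calib) {
  stopifnot(inherits(calib, "fm_calibration"))
  ph <- calib$phases
  stat_row <- ph[ph$phase == "static", , drop = FALSE]
  hinge_rows <- ph[grepl("^hinge", ph$phase), , drop = FALSE]
  if (nrow(stat_row) != 1L || nrow(hinge_rows) < 1L)
    stop("calibration must contain a static phase and at least one hinge phase")
  n_sensors <- dim(calib$acc)[3]
  g_mag <- gravity_vec()[1]
  out <- vector("list", n_sensors)
  for (s in seq_len(n_sensors)) {
    idx_stat <- seq.int(stat_row$start_sample, stat_row$end_sample)
    acc_mean <- colMeans(calib$acc[idx_stat, , s])
    mag <- sqrt(sum(acc_mean^2))
    if (abs(mag - g_mag) > 0.2 * g_mag)
      stop(sprintf("sensor %d not static during calibration: mean |acc| = %.2f m/s^2", s, mag))
    x_axis <- acc_mean / mag

    idx_hinge <- unlist(lapply(seq_len(nrow(hinge_rows)), function(h)
      seq.int(hinge_rows$start_sample[h], hinge_rows$end_sample[h])))
    gh <- calib$gyr[idx_hinge, , s]
    if (max(sqrt(rowSums(gh^2))) < 0.1)
      stop(sprintf("degenerate hinge rotation for sensor %d: peak angular rate < 0.1 rad/s", s))
    cen <- sweep(gh, 2L, colMeans(gh))
    ev <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)
    w <- ev$vectors[, 1]
    y_axis <- w - sum(w * x_axis) * x_axis
    y_norm <- sqrt(sum(y_axis^2))
    if (y_norm < 1e-6)
      stop(sprintf("hinge rotation axis parallel to gravity for sensor %d", s))
    y_axis <- y_axis / y_norm
    # sign: the forward lean is the faster rotation, so the sample with the
    # largest projected angular rate should project positively
    proj <- gh %*% y_axis
    if (proj[which.max(abs(proj))] < 0) y_axis <- -y_axis
    z_axis <- c(x_axis[2] * y_axis[3] - x_axis[3] * y_axis[2],
                x_axis[3] * y_axis[1] - x_axis[1] * y_axis[3],
                x_axis[1] * y_axis[2] - x_axis[2] * y_axis[1])
    out[[s]] <- cbind(x_axis, y_axis, z_axis, deparse.level = 0)
  }
  structure(out, class = "fm_alignment")
}

#' Apply alignment transforms to gyroscope data
#'
#' Rotates each sensor's angular-rate samples into the anatomical frame
#' (x gravity, y frontal, z sagittal).  Rotation is an isometry, so sample
#' norms are preserved.  Acceleration data are deliberately left unaligned
#' by the pipeline: realignment would mix the axis tangential to the
#' abdomen, where localized fetal deformation is most visible, into the
#' other axes.
#'
#' @param gyr Array `[n_samples, 3, n_sensors]` of angular rates.
#' @param transform An `fm_alignment` (one matrix per sensor).
#' @return Array of the same shape, rotated sensor-wise.
#' @export
apply_alignment <- function(gyr, transform) {
  stopifnot(inherits(transform, "fm_alignment"))
  n_sensors <- dim(gyr)[3]
  if (length(transform) != n_sensors)
    stop(sprintf("missing alignment transform: have %d, need %d sensors",
                 length(transform), n_sensors))
  out <- gyr
  for (s in seq_len(n_sensors)) out[, , s] <- gyr[, , s] %*% transform[[s]]
  out
}

#' Preprocess one trial
#'
#' Runs the standard preprocessing chain: zero-phase bandpass filtering of
#' all acceleration and angular-rate channels, then functional alignment
#' of the (filtered) gyroscope axes using transforms estimated from the
#' raw calibration recording.  Acceleration axes are not realigned.
#'
#' @param trial An `fm_trial`.
#' @param calib The trial's `fm_calibration`.
#' @param spec An [filter_spec()].
#' @return The trial with filtered `acc`, filtered + aligned `gyr`, and the
#'   estimated `alignment` attached.
#' @export
preprocess_trial <- function(trial, calib, spec = filter_spec()) {
  stopifnot(inherits(trial, "fm_trial"))
  transform <- estimate_alignment(calib)
  trial$acc <- bandpass_zero_phase(trial$acc, trial$fs, spec)
  trial$gyr <- apply_alignment(bandpass_zero_phase(trial$gyr, trial$fs, spec),
                               transform)
  trial$alignment <- transform
  trial
}
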