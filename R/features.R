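#' Names of the 75 hand-engineered features (one modality)
#'
#' The canonical feature set per modality decomposes as: per-sensor
#' per-axis statistics (mean, standard deviation, range) over all five
#' sensors = 45; within-sensor axis-pair Pearson correlations (xy, xz, yz)
#' for each sensor = 15; maximum-magnitude normalized cross-correlation
#' over all lags between each abdominal axis and the same reference-sensor
#' axis = 12; Pearson correlation between each axis of the abdominal-mean
#' signal and the same reference axis = 3.  Total 75.
#'
#' @param n_abdominal Number of abdominal sensors (default 4).
#' @return Character vector of length 75.
#' @export
feature_names <- function(n_abdominal = 4L) {
  sensors <- c(paste0("abd", seq_len(n_abdominal)), "ref")
  axes <- c("x", "y", "z")
  stats <- as.vector(t(outer(sensors, axes, function(s, a)
    paste0(s, "_", a, "_"))))
  stats <- as.vector(sapply(stats, function(p) paste0(p, c("mean", "sd", "range"))))
  pairs <- as.vector(sapply(sensors, function(s)
    paste0(s, "_cor_", c("xy", "xz", "yz"))))
  xcors <- as.vector(sapply(paste0("abd", seq_len(n_abdominal)), function(s)
    paste0(s, "_", axes, "_xcorr_ref")))
  mcors <- paste0("abdmean_", axes, "_cor_ref")
  c(stats, pairs, xcors, mcors)
}

# Pearson correlation with the degenerate (zero-variance) convention -> 0.
safe_cor <- function(x, y) {
  sx <- sd(x); sy <- sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(0)
  cor(x, y)
}

# Normalized cross-correlation over all lags; returns the signed value at
# the lag of maximum magnitude.  Both signals are mean-centred and the
# product is normalized by the signal energies, so the result is bounded
# in [-1, 1] (Cauchy-Schwarz); zero-variance inputs map to 0.
max_xcorr <- function(x, y) {
  x0 <- x - mean(x); y0 <- y - mean(y)
  ex <- sqrt(sum(x0^2)); ey <- sqrt(sum(y0^2))
  if (ex == 0 || ey == 0) return(0)
  cc <- convolve(x0, y0, type = "open") / (ex * ey)
  cc[which.max(abs(cc))]
}

#' Extract the 75 hand-engineered features from one window
#'
#' Computes statistical and correlation features for each axis and sensor
#' of a single fixed-length window: mean, standard deviation, and range
#' per channel; cross-correlation between axes within each sensor; and
#' cross-correlation with the chest reference sensor for each axis.  The
#' result has exactly 75 named features per modality (see
#' [feature_names()] for the canonical order).
#'
#' @param window Array `[n_samples, 3, n_sensors]` for one modality, with
#'   the chest reference as the last sensor.
#' @param reference Index of the reference sensor (default: last).
#' @return Named numeric vector of length 75.
#' @examples
#' w <- array(rnorm(64 * 3 * 5), dim = c(64, 3, 5))
#' length(extract_features(w))  # 75
#' @export
extract_features <- function(window, reference = dim(window)[3]) {
  d <- dim(window)
  if (is.null(d) || length(d) != 3L || d[2] != 3L)
    stop("window must be an [n_samples, 3, n_sensors] array")
  if (d[1] < 2L) stop("window must have at least 2 samples")
  if (anyNA(window)) stop("window contains NA values")
  n_sensors <- d[3]
  abdominal <- setdiff(seq_len(n_sensors), reference)

  vals <- numeric(0)
  for (s in seq_len(n_sensors)) for (a in 1:3) {
    ch <- window[, a, s]
    vals <- c(vals, mean(ch), sd(ch), max(ch) - min(ch))
  }
  for (s in seq_len(n_sensors)) {
    vals <- c(vals,
              safe_cor(window[, 1, s], window[, 2, s]),
              safe_cor(window[, 1, s], window[, 3, s]),
              safe_cor(window[, 2, s], window[, 3, s]))
  }
  for (s in abdominal) for (a in 1:3) {
    vals <- c(vals, max_xcorr(window[, a, s], window[, a, reference]))
  }
  abd_mean <- apply(window[, , abdominal, drop = FALSE], c(1, 2), mean)
  for (a in 1:3) {
    vals <- c(vals, safe_cor(abd_mean[, a], window[, a, reference]))
  }
  names(vals) <- feature_names(length(abdominal))
  vals
}

#' Feature matrix for all windows of a trial
#'
#' Applies [extract_features()] to every window on a grid, for one
#' modality or both concatenated (acceleration features first, prefixed
#' `acc_`/`gyr_`; 150 columns when combined).
#'
#' @param trial A (preprocessed) `fm_trial`.
#' @param grid An `fm_grid` from [segment_windows()].
#' @param modality One of `"acc"`, `"gyr"`, `"combined"`.
#' @return Numeric matrix `[n_windows, 75 or 150]` with feature-name
#'   columns.
#' @export
extract_feature_matrix <- function(trial, grid,
                                   modality = c("combined", "acc", "gyr")) {
  modality <- match.arg(modality)
  mods <- if (modality == "combined") c("acc", "gyr") else modality
  ref <- trial$sensor_roles$reference
  blocks <- lapply(mods, function(m) {
    sig <- trial[[m]]
    out <- t(vapply(seq_len(nrow(grid)), function(i) {
      i0 <- grid$start_sample[i]
      w <- sig[i0:(i0 + grid$n_window_samples[i] - 1L), , , drop = FALSE]
      extract_features(w, reference = ref)
    }, numeric(75L)))
    colnames(out) <- paste0(m, "_", colnames(out))
    out
  })
  do.call(cbind, blocks)
}
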