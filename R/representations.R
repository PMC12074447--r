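#' Build raw time-series tensors for a window grid
#'
#' Stacks the raw (preprocessed) samples of every 0.5 s window into an
#' array `[n_windows, n_samples, n_channels]`.  Channels are ordered
#' sensor-major within each modality (sensor 1 x/y/z, sensor 2 x/y/z, ...);
#' the combined modality concatenates acceleration channels then angular
#' rate channels (15 + 15 = 30).
#'
#' @param trial A (preprocessed) `fm_trial`.
#' @param grid An `fm_grid` from [segment_windows()].
#' @param modality One of `"acc"`, `"gyr"`, `"combined"`.
#' @return Numeric array `[n_windows, window_samples, channels]`.
#' @export
build_timeseries_tensors <- function(trial, grid,
                                     modality = c("combined", "acc", "gyr")) {
  modality <- match.arg(modality)
  mods <- if (modality == "combined") c("acc", "gyr") else modality
  win <- grid$n_window_samples[1]
  n_win <- nrow(grid)
  blocks <- lapply(mods, function(m) {
    sig <- trial[[m]]
    d <- dim(sig)
    flat <- matrix(sig, nrow = d[1])          # channels = axis-within-sensor... fix order below
    # column order of `flat` is [axis varies fastest? no: dim (n,3,S) flattens
    # axis-major per sensor: columns are (a1s1,a2s1,a3s1,a1s2,...)] which is
    # the sensor-major x/y/z ordering we document.
    arr <- array(0, dim = c(n_win, win, d[2] * d[3]))
    for (i in seq_len(n_win)) {
      i0 <- grid$start_sample[i]
      arr[i, , ] <- flat[i0:(i0 + win - 1L), ]
    }
    arr
  })
  out <- if (length(blocks) == 1L) blocks[[1]] else {
    arr <- array(0, dim = c(n_win, win, sum(vapply(blocks, function(b) dim(b)[3], 0))))
    arr[, , seq_len(dim(blocks[[1]])[3])] <- blocks[[1]]
    arr[, , dim(blocks[[1]])[3] + seq_len(dim(blocks[[2]])[3])] <- blocks[[2]]
    arr
  }
  out
}

#' Per-channel standardization statistics from a training tensor set
#'
#' @param tensors Array `[n_windows, n_samples, channels]` of training
#'   windows only (statistics must never be computed on validation or test
#'   data).
#' @return List with `mean` and `sd` per channel (class
#'   `fm_standardizer`).
#' @export
fit_standardizer <- function(tensors) {
  ch_mean <- apply(tensors, 3L, mean)
  ch_sd <- apply(tensors, 3L, sd)
  ch_sd[ch_sd == 0] <- 1
  structure(list(mean = ch_mean, sd = ch_sd), class = "fm_standardizer")
}

#' Apply per-channel standardization
#'
#' @param tensors Array `[n_windows, n_samples, channels]`.
#' @param standardizer From [fit_standardizer()] (training statistics).
#' @return Standardized array of the same shape.
#' @export
apply_standardizer <- function(tensors, standardizer) {
  stopifnot(inherits(standardizer, "fm_standardizer"))
  for (c in seq_len(dim(tensors)[3])) {
    tensors[, , c] <- (tensors[, , c] - standardizer$mean[c]) / standardizer$sd[c]
  }
  tensors
}

# Symmetric Hann window of length n.
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))

# Core STFT: one-sided magnitude with a sliding 16-sample Hann window and
# stride 1.  x is a matrix [n_samples, channels]; returns
# [n_bins = nfft/2 + 1, n_frames = n_samples - nfft + 1, channels].
stft_magnitude <- function(x, nfft = 16L) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  if (n < nfft) stop("signal shorter than the STFT window")
  n_frames <- n - nfft + 1L
  n_bins <- nfft %/% 2L + 1L
  win <- hann_window(nfft)
  idx <- outer(seq_len(nfft), seq_len(n_frames) - 1L, "+")
  out <- array(0, dim = c(n_bins, n_frames, ncol(x)))
  for (ch in seq_len(ncol(x))) {
    frames <- matrix(x[idx, ch], nrow = nfft) * win
    spec <- mvfft(frames)
    out[, , ch] <- Mod(spec[seq_len(n_bins), , drop = FALSE])
  }
  out
}

#' Compute the magnitude spectrogram stack of one 8 s window
#'
#' Short-time Fourier transform with a sliding 16-sample Hann window and a
#' stride of one sample; the one-sided magnitude is retained.  For an 8 s
#' window at 128 Hz (1024 samples) the result has 16/2 + 1 = 9 frequency
#' bins (spacing fs/16 = 8 Hz) and 1024 - 16 + 1 = 1009 frames.
#'
#' @param window Matrix `[1024, channels]` (or a vector for one channel).
#' @param fs Sampling rate in Hz (default 128).
#' @return Array `[9, 1009, channels]` of non-negative magnitudes, with a
#'   `freqs` attribute giving the bin frequencies in Hz.
#' @examples
#' x <- sin(2 * pi * 8 * (0:1023) / 128)
#' s <- compute_spectrogram(x)
#' dim(s)  # 9 1009 1
#' @export
compute_spectrogram <- function(window, fs = 128) {
  if (is.null(dim(window))) window <- matrix(window, ncol = 1L)
  if (nrow(window) != round(8 * fs))
    stop(sprintf("spectrogram windows must have exactly %d samples (8 s at %g Hz), got %d",
                 round(8 * fs), fs, nrow(window)))
  out <- stft_magnitude(window, nfft = 16L)
  attr(out, "freqs") <- (seq_len(dim(out)[1]) - 1) * fs / 16
  out
}

#' Trial-level spectrogram for efficient window slicing
#'
#' Computes the stride-1 STFT once over the whole trial; because the frame
#' hop is one sample, the spectrogram of any 8 s window is exactly a
#' contiguous block of trial frames, so [slice_spectrogram_windows()] can
#' cut per-window stacks without recomputation.
#'
#' @param trial A (preprocessed) `fm_trial`.
#' @param modality One of `"acc"`, `"gyr"`, `"combined"`.
#' @return Array `[9, n_samples - 15, channels]`.
#' @export
trial_spectrogram <- function(trial, modality = c("combined", "acc", "gyr")) {
  modality <- match.arg(modality)
  mods <- if (modality == "combined") c("acc", "gyr") else modality
  blocks <- lapply(mods, function(m) {
    sig <- trial[[m]]
    stft_magnitude(matrix(sig, nrow = dim(sig)[1]), nfft = 16L)
  })
  if (length(blocks) == 1L) return(blocks[[1]])
  d1 <- dim(blocks[[1]]); d2 <- dim(blocks[[2]])
  out <- array(0, dim = c(d1[1], d1[2], d1[3] + d2[3]))
  out[, , seq_len(d1[3])] <- blocks[[1]]
  out[, , d1[3] + seq_len(d2[3])] <- blocks[[2]]
  out
}

#' Slice per-window spectrogram stacks from a trial-level spectrogram
#'
#' @param trial_spec Array from [trial_spectrogram()].
#' @param grid An 8 s `fm_grid` (stride in samples defines the frame
#'   offsets).
#' @param fs Sampling rate (default 128); frames per window is
#'   `8 * fs - 15`.
#' @return Array `[n_windows, 9, frames, channels]`.
#' @export
slice_spectrogram_windows <- function(trial_spec, grid, fs = 128) {
  n_frames <- round(8 * fs) - 15L
  d <- dim(trial_spec)
  n_win <- nrow(grid)
  out <- array(0, dim = c(n_win, d[1], n_frames, d[3]))
  for (i in seq_len(n_win)) {
    f0 <- grid$start_sample[i]
    out[i, , , ] <- trial_spec[, f0:(f0 + n_frames - 1L), ]
  }
  out
}

#' Per-bin spectrogram standardizer from training trials
#'
#' Computes the mean and standard deviation of the spectrogram magnitude
#' in every (frequency bin, channel) cell over the frames of the training
#' trials.  Standardizing with these statistics puts all bins on a common
#' scale; raw magnitudes span orders of magnitude between the
#' low-frequency bins (dominated by maternal motion) and the bins carrying
#' fetal-burst energy, which destabilizes gradient training.
#'
#' @param trial_specs List of trial-level spectrograms
#'   (`[bins, frames, channels]`) from [trial_spectrogram()].
#' @param train_ids Indices of the training trials (statistics must never
#'   include validation or test trials).
#' @return List of class `fm_spec_standardizer` with `center` and `scale`
#'   matrices (`bins x channels`).
#' @export
fit_spec_standardizer <- function(trial_specs, train_ids) {
  d <- dim(trial_specs[[train_ids[1]]])
  nb <- d[1] * d[3]
  s1 <- numeric(nb); s2 <- numeric(nb); nf <- 0
  for (i in train_ids) {
    m <- matrix(aperm(trial_specs[[i]], c(1, 3, 2)), nrow = nb)
    s1 <- s1 + rowSums(m)
    s2 <- s2 + rowSums(m^2)
    nf <- nf + ncol(m)
  }
  mu <- s1 / nf
  sdv <- sqrt(pmax(s2 / nf - mu^2, 0))
  sdv[sdv == 0] <- 1
  structure(list(center = matrix(mu, d[1], d[3]),
                 scale = matrix(sdv, d[1], d[3])),
            class = "fm_spec_standardizer")
}

#' Per-channel max-magnitude normalizer for spectrogram stacks
#'
#' Spectrograms are normalized by the per-channel maximum magnitude of the
#' training set (raw magnitudes, no log transform).
#'
#' @param spec_windows Array `[n_windows, bins, frames, channels]` of
#'   training windows.
#' @return Class `fm_spec_normalizer` with per-channel scale factors.
#' @export
fit_spec_normalizer <- function(spec_windows) {
  scale <- apply(spec_windows, 4L, max)
  scale[scale == 0] <- 1
  structure(list(scale = scale), class = "fm_spec_normalizer")
}

#' @rdname fit_spec_normalizer
#' @param normalizer A fitted `fm_spec_normalizer`.
#' @export
apply_spec_normalizer <- function(spec_windows, normalizer) {
  stopifnot(inherits(normalizer, "fm_spec_normalizer"))
  for (c in seq_len(dim(spec_windows)[4])) {
    spec_windows[, , , c] <- spec_windows[, , , c] / normalizer$scale[c]
  }
  spec_windows
}
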