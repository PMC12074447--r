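#' Convert button presses to fetal movement event intervals
#'
#' Each recorded perception press at time `t` defines the event interval
#' `[t - 3.5, t + 1.5]` seconds, accounting for maternal reaction time and
#' fetal movement duration.  Overlapping intervals are kept as-is; the
#' union is taken only when computing window overlap.
#'
#' @param press_times Numeric vector of press times (s).
#' @param before,after Seconds before/after the press (defaults 3.5, 1.5).
#' @return A data.frame with columns `start`, `end` (one row per press).
#' @examples
#' presses_to_events(10)   # [6.5, 11.5]
#' @export
presses_to_events <- function(press_times, before = 3.5, after = 1.5) {
  data.frame(start = press_times - before, end = press_times + after)
}

#' Segment a trial into a fixed window grid
#'
#' Windows start at t = 0 and advance by `stride`; a final partial window
#' is dropped.  All arithmetic is carried out in samples to avoid
#' floating-point grid drift.
#'
#' @param n_samples Number of samples in the trial (or an `fm_trial`).
#' @param window_len Window length in seconds (0.5 for the feature/time
#'   series representations, 8 for the spectrogram representation).
#' @param stride Stride in seconds (equal to `window_len` for no overlap).
#' @param fs Sampling rate in Hz.
#' @return A data.frame of class `fm_grid` with columns `grid_index`
#'   (0-based), `start_s`, `start_sample` (1-based), `n_window_samples`;
#'   attributes `fs` and `n_samples`.
#' @export
segment_windows <- function(n_samples, window_len, stride, fs = 128) {
  if (inherits(n_samples, "fm_trial")) {
    fs <- n_samples$fs
    n_samples <- dim(n_samples$acc)[1]
  }
  if (stride <= 0) stop("stride must be positive")
  win <- round(window_len * fs)
  hop <- round(stride * fs)
  if (win > n_samples)
    stop("window_len exceeds trial duration")
  n_win <- (n_samples - win) %/% hop + 1L
  idx <- seq_len(n_win) - 1L
  grid <- data.frame(
    grid_index = idx,
    start_s = idx * hop / fs,
    start_sample = idx * hop + 1L,
    n_window_samples = win
  )
  attr(grid, "fs") <- fs
  attr(grid, "n_samples") <- n_samples
  class(grid) <- c("fm_grid", "data.frame")
  grid
}

# Logical vector over samples: TRUE where the sample time lies inside the
# union of the (clipped) event intervals.  Sample k (1-based) has time
# (k-1)/fs; an event [a, b) covers samples with a <= t < b.
event_sample_mask <- function(events, n_samples, fs) {
  mask <- logical(n_samples)
  if (NROW(events) == 0) return(mask)
  dur <- n_samples / fs
  for (e in seq_len(nrow(events))) {
    a <- max(0, events$start[e])
    b <- min(dur, events$end[e])
    if (b <= a) next
    k0 <- ceiling(a * fs - 1e-9) + 1L
    k1 <- ceiling(b * fs - 1e-9)
    if (k1 >= k0) mask[k0:min(k1, n_samples)] <- TRUE
  }
  mask
}

#' Label windows by fractional overlap with event intervals
#'
#' A window is labeled 1 when strictly more than `overlap_frac` of its
#' samples fall inside the union of the event intervals (events are
#' clipped to the trial and unioned so overlapping presses never count
#' twice), and 0 otherwise.  Overlap is evaluated at exact sample
#' resolution on the recording grid.
#'
#' @param grid An `fm_grid` from [segment_windows()].
#' @param events A data.frame with `start`/`end` columns (seconds), e.g.
#'   from [presses_to_events()].
#' @param overlap_frac Overlap fraction threshold, strictly exceeded for a
#'   positive label (default 0.1).
#' @return Integer vector of labels in {0, 1}, one per window.
#' @export
label_windows <- function(grid, events, overlap_frac = 0.1) {
  stopifnot(inherits(grid, "fm_grid"))
  if (overlap_frac <= 0 || overlap_frac >= 1)
    stop("overlap_frac must lie in (0, 1)")
  fs <- attr(grid, "fs")
  n_samples <- attr(grid, "n_samples")
  mask <- event_sample_mask(events, n_samples, fs)
  cs <- c(0L, cumsum(mask))
  counts <- cs[grid$start_sample + grid$n_window_samples] - cs[grid$start_sample]
  as.integer(counts > overlap_frac * grid$n_window_samples)
}

#' Rebalance a training window set by discarding negatives
#'
#' Discards `drop_fraction` of the negatively labeled windows uniformly at
#' random (all positives are kept), the mechanism used to bring the
#' positive:negative ratio in the training partition to roughly 1:3 when
#' about 11% of windows are positive.  Applies to the training partition
#' only; validation and test sets keep their natural prevalence.
#'
#' @param labels Integer vector of window labels in {0, 1}.
#' @param drop_fraction Fraction of negatives to discard (default 2/3).
#' @param seed Integer seed making the subsample deterministic.
#' @return Sorted integer indices of the retained windows.
#' @export
rebalance_training <- function(labels, drop_fraction = 2 / 3, seed = 1L) {
  stopifnot(all(labels %in% c(0L, 1L)))
  if (drop_fraction < 0 || drop_fraction >= 1)
    stop("drop_fraction must lie in [0, 1)")
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  if (length(pos) == 0L) {
    warning("no positive windows; returning the input unchanged")
    return(seq_along(labels))
  }
  if (drop_fraction == 0) return(seq_along(labels))
  n_drop <- round(drop_fraction * length(neg))
  set.seed(seed)
  dropped <- sample(neg, n_drop)
  sort(c(pos, setdiff(neg, dropped)))
}
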