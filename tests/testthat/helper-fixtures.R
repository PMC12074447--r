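# Shared fixtures built in code at test time.

# Clean configuration: no noise, no drift, no events, identity mountings.
quiet_config <- function(duration = 20, ...) {
  sim_config(trial_duration = duration, event_rate = 0, noise_sd_acc = 0,
             noise_sd_gyr = 0, drift_scale = 0,
             mounting_rotations = replicate(5, diag(3), simplify = FALSE),
             ...)
}

# Brute-force per-sample labeling oracle, deliberately a different code
# path from label_windows(): vectorized membership test per event, then a
# per-window sample count via an explicit window loop.
oracle_labels <- function(grid, events, overlap_frac = 0.1) {
  fs <- attr(grid, "fs")
  n_samples <- attr(grid, "n_samples")
  t_k <- (seq_len(n_samples) - 1) / fs
  dur <- n_samples / fs
  in_event <- rep(FALSE, n_samples)
  if (NROW(events) > 0) {
    for (e in seq_len(nrow(events))) {
      a <- max(0, events$start[e]); b <- min(dur, events$end[e])
      in_event <- in_event | (t_k >= a & t_k < b)
    }
  }
  vapply(seq_len(nrow(grid)), function(i) {
    idx <- grid$start_sample[i] + seq_len(grid$n_window_samples[i]) - 1L
    as.integer(sum(in_event[idx]) > overlap_frac * grid$n_window_samples[i])
  }, integer(1))
}

# Trapezoidal area under the empirical ROC curve, an independent oracle
# for the rank-statistic AUROC.
oracle_auroc_trapezoid <- function(labels, scores) {
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tpr <- vapply(ths, function(th) sum(scores >= th & labels == 1) / n1, 0)
  fpr <- vapply(ths, function(th) sum(scores >= th & labels == 0) / n0, 0)
  tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Small, quickly learnable time-series task: positives carry a 5 Hz burst.
easy_timeseries_task <- function(n, seed) {
  set.seed(seed)
  x <- array(rnorm(n * 64 * 3), dim = c(n, 64, 3))
  y <- rbinom(n, 1, 0.5)
  t <- (0:63) / 128
  for (i in which(y == 1)) x[i, , 1] <- x[i, , 1] + 2 * sin(2 * pi * 5 * t)
  list(x = x, y = y)
}

# Small, quickly learnable spectrogram task: positives carry a band-limited
# burst in a single-channel 8 s window.
easy_spectrogram_task <- function(n, seed) {
  set.seed(seed)
  t <- (0:1023) / 128
  y <- rbinom(n, 1, 0.5)
  specs <- array(0, dim = c(n, 9, 1009, 1))
  for (i in seq_len(n)) {
    sig <- rnorm(1024, sd = 0.5)
    if (y[i] == 1) {
      on <- sample(1:512, 1)
      idx <- on:(on + 255)
      sig[idx] <- sig[idx] + 2 * sin(2 * pi * 6 * t[idx])
    }
    specs[i, , , 1] <- compute_spectrogram(sig)
  }
  list(x = specs, y = y)
}
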