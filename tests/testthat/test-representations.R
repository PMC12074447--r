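test_that("time-series tensors have the documented channel layout", {
  cfg <- sim_config(trial_duration = 10, event_rate = 0.2)
  tr <- simulate_trial(cfg, seed = 4)$trial
  grid <- segment_windows(tr, 0.5, 0.5)
  tc <- build_timeseries_tensors(tr, grid, "combined")
  expect_equal(dim(tc), c(nrow(grid), 64L, 30L))
  ta <- build_timeseries_tensors(tr, grid, "acc")
  expect_equal(dim(ta), c(nrow(grid), 64L, 15L))
  expect_equal(tc[, , 1:15], ta)
  # channel 1 is sensor 1 axis x of the acceleration signal
  expect_equal(ta[3, , 1], tr$acc[grid$start_sample[3] + 0:63, 1, 1])
  # channel 16 of combined is sensor 1 axis x of the angular rate signal
  expect_equal(tc[3, , 16], tr$gyr[grid$start_sample[3] + 0:63, 1, 1])
})

test_that("standardization uses training statistics and centers them", {
  set.seed(1)
  train <- array(rnorm(50 * 64 * 3, mean = 2, sd = 4), dim = c(50, 64, 3))
  std <- fit_standardizer(train)
  z <- apply_standardizer(train, std)
  for (c in 1:3) {
    expect_equal(mean(z[, , c]), 0, tolerance = 1e-10)
    expect_equal(sd(as.vector(z[, , c])), 1, tolerance = 1e-2)
  }
  test_arr <- array(rnorm(10 * 64 * 3), dim = c(10, 64, 3))
  z2 <- apply_standardizer(test_arr, std)
  expect_equal(z2[, , 1], (test_arr[, , 1] - std$mean[1]) / std$sd[1])
})

test_that("spectrograms have the contractual shape and bin placement", {
  x <- matrix(rnorm(1024 * 15), 1024, 15)
  s <- compute_spectrogram(x)
  expect_equal(dim(s), c(9L, 1009L, 15L))
  expect_true(all(s >= 0))
  expect_equal(attr(s, "freqs"), seq(0, 64, by = 8))
  # a pure 8 Hz tone peaks in bin index 1 (0-based; spacing fs/16 = 8 Hz)
  tone <- sin(2 * pi * 8 * (0:1023) / 128)
  st <- compute_spectrogram(tone)
  expect_equal(unname(which.max(rowMeans(st[, , 1]))) - 1L, 1L)
  # zero input gives an all-zero spectrogram
  expect_true(all(compute_spectrogram(matrix(0, 1024, 2)) == 0))
  expect_error(compute_spectrogram(matrix(0, 500, 2)), "1024")
})

test_that("spectrogram magnitude scales linearly with input amplitude", {
  set.seed(3)
  x <- rnorm(1024)
  s1 <- compute_spectrogram(x)
  s3 <- compute_spectrogram(-3 * x)
  expect_equal(s3, 3 * s1, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("trial-level spectrogram slicing equals per-window computation", {
  cfg <- sim_config(trial_duration = 12, event_rate = 0.3)
  tr <- simulate_trial(cfg, seed = 6)$trial
  grid <- segment_windows(tr, 8, 1)
  tsp <- trial_spectrogram(tr, "acc")
  expect_equal(dim(tsp), c(9L, dim(tr$acc)[1] - 15L, 15L))
  sliced <- slice_spectrogram_windows(tsp, grid)
  for (i in seq_len(nrow(grid))) {
    w <- matrix(tr$acc[grid$start_sample[i] + 0:1023, , ], 1024)
    direct <- compute_spectrogram(w)
    expect_equal(sliced[i, , , ], direct, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("lazy window sets fetch the same stacks as dense arrays", {
  cfg <- sim_config(trial_duration = 12, event_rate = 0.3)
  tr <- simulate_trial(cfg, seed = 6)$trial
  grid <- segment_windows(tr, 8, 1)
  tsp <- trial_spectrogram(tr, "gyr")
  sw <- spec_window_set(list(tsp), rep(1L, nrow(grid)), grid$start_sample)
  src <- fmdetect:::as_spec_source(sw)
  dense <- slice_spectrogram_windows(tsp, grid)
  got <- src$fetch(c(2L, 4L))
  expect_equal(got[, , , 1], dense[2, , , ])
  expect_equal(got[, , , 2], dense[4, , , ])
})

test_that("spectrogram normalizer scales channels by the training maximum", {
  set.seed(8)
  sp <- array(abs(rnorm(5 * 9 * 20 * 2)), dim = c(5, 9, 20, 2))
  nrm <- fit_spec_normalizer(sp)
  expect_equal(nrm$scale, c(max(sp[, , , 1]), max(sp[, , , 2])))
  out <- apply_spec_normalizer(sp, nrm)
  expect_equal(max(out), 1)
})
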