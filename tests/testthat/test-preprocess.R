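test_that("zero-phase bandpass matches its designed frequency response", {
  fs <- 128
  t <- (0:4095) / fs
  for (f in c(0.1, 5, 10, 18, 40)) {
    y <- bandpass_zero_phase(sin(2 * pi * f * t), fs)
    measured <- max(abs(y[500:3500]))
    expected <- bandpass_response(f, fs)
    expect_equal(measured, expected, tolerance = 0.02)
  }
  # passband: within 1 dB and zero lag
  y10 <- bandpass_zero_phase(sin(2 * pi * 10 * t), fs)
  expect_gt(20 * log10(max(abs(y10[500:3500]))), -1)
  cc <- ccf(y10[500:3500], sin(2 * pi * 10 * t)[500:3500], lag.max = 10,
            plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # stopband: at least 20 dB down
  for (f in c(0.1, 40)) {
    y <- bandpass_zero_phase(sin(2 * pi * f * t), fs)
    expect_lt(20 * log10(max(abs(y[500:3500]))), -20)
  }
})

test_that("constant input is rejected to numerical zero", {
  out <- bandpass_zero_phase(rep(7, 1000), 128)
  expect_lt(max(abs(out)), 1e-6 * 7)
})

test_that("too-short signals raise an informative error", {
  expect_error(bandpass_zero_phase(rnorm(10), 128), "at least|more than|samples")
})

test_that("alignment recovers the mounting rotation", {
  # identity, noiseless
  cal <- simulate_calibration(quiet_config(), seed = 5)
  al <- estimate_alignment(cal)
  for (s in 1:5) expect_lt(max(abs(al[[s]] - diag(3))), 1e-6)

  # known 30-degree mounting about sensor z, noiseless: estimate = inverse
  R30 <- fmdetect:::rotation_about_axis(c(0, 0, 1), 30 * pi / 180)
  cfg30 <- sim_config(trial_duration = 20, event_rate = 0, noise_sd_acc = 0,
                      noise_sd_gyr = 0, drift_scale = 0,
                      mounting_rotations = replicate(5, R30, simplify = FALSE))
  al30 <- estimate_alignment(simulate_calibration(cfg30, seed = 5))
  for (s in 1:5) {
    D <- crossprod(al30[[s]], t(R30))     # should be the identity
    ang <- acos(min(1, (sum(diag(D)) - 1) / 2)) * 180 / pi
    expect_lt(ang, 0.1)
  }
})

test_that("alignment recovery stays within 2 degrees under default noise", {
  cfg <- sim_config(trial_duration = 20)
  worst <- 0
  for (s in 1:25) {
    cal <- simulate_calibration(cfg, seed = 100 + s)
    al <- estimate_alignment(cal)
    for (k in 1:5) {
      D <- crossprod(al[[k]], t(cal$mounting[[k]]))
      ang <- acos(min(1, max(-1, (sum(diag(D)) - 1) / 2))) * 180 / pi
      worst <- max(worst, ang)
    }
  }
  expect_lt(worst, 2)
})

test_that("alignment transforms are orthonormal and right-handed", {
  cal <- simulate_calibration(sim_config(trial_duration = 20), seed = 31)
  al <- estimate_alignment(cal)
  for (s in 1:5) {
    expect_lt(max(abs(crossprod(al[[s]]) - diag(3))), 1e-6)
    expect_equal(det(al[[s]]), 1, tolerance = 1e-9)
  }
})

test_that("alignment errors: non-static sensor and degenerate hinge", {
  cal <- simulate_calibration(quiet_config(), seed = 5)
  bad <- cal; bad$acc <- bad$acc * 2
  expect_error(estimate_alignment(bad), "not static")
  flat <- cal; flat$gyr[] <- 0
  expect_error(estimate_alignment(flat), "degenerate|hinge")
})

test_that("apply_alignment is an isometry and inverts cleanly", {
  cal <- simulate_calibration(sim_config(trial_duration = 20), seed = 8)
  al <- estimate_alignment(cal)
  gyr <- array(rnorm(200 * 3 * 5), dim = c(200, 3, 5))
  out <- apply_alignment(gyr, al)
  # identity transform leaves data unchanged
  id <- structure(replicate(5, diag(3), simplify = FALSE), class = "fm_alignment")
  expect_identical(apply_alignment(gyr, id), gyr)
  # norms preserved per sample
  expect_lt(max(abs(sqrt(rowSums(out[, , 1]^2)) - sqrt(rowSums(gyr[, , 1]^2)))), 1e-9)
  # transform then inverse recovers the input
  inv <- structure(lapply(al, t), class = "fm_alignment")
  back <- apply_alignment(out, inv)
  expect_lt(max(abs(back - gyr)), 1e-9)
  # missing transform errors
  expect_error(apply_alignment(gyr, structure(al[1:3], class = "fm_alignment")),
               "missing")
})

test_that("aligned rigid-body gyroscopes agree across sensors", {
  cfg <- sim_config(trial_duration = 20, event_rate = 0, noise_sd_acc = 0,
                    noise_sd_gyr = 0, drift_scale = 0,
                    maternal_burst_rate = 0.4)
  tr <- simulate_trial(cfg, seed = 13)$trial
  cal <- simulate_calibration(cfg, seed = 13)
  proc <- preprocess_trial(tr, cal)
  for (s in 2:5)
    expect_lt(max(abs(proc$gyr[, , s] - proc$gyr[, , 1])), 1e-6)
})

test_that("fetal events raise across-sensor gyroscope disagreement", {
  cfg <- sim_config(trial_duration = 60, event_rate = 0.3,
                    p_perceive = 1, reaction_delay_sd = 0.1)
  sim <- simulate_trial(cfg, seed = 17)
  cal <- simulate_calibration(cfg, seed = 17)
  proc <- preprocess_trial(sim$trial, cal)
  abd <- proc$gyr[, , 1:4]
  disagreement <- rowSums(apply(abd, c(1, 2), var))
  n <- dim(proc$gyr)[1]
  mask <- rep(FALSE, n)
  for (e in seq_along(sim$truth$event_onsets)) {
    i0 <- floor(sim$truth$event_onsets[e] * cfg$fs) + 1L
    i1 <- min(n, floor((sim$truth$event_onsets[e] + sim$truth$event_durations[e]) * cfg$fs))
    mask[i0:i1] <- TRUE
  }
  expect_gt(mean(disagreement[mask]), 2 * mean(disagreement[!mask]))
})
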