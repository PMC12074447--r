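test_that("perception contracts: none at p = 0, identity at p = 1 with zero delay", {
  cfg0 <- sim_config(trial_duration = 60, event_rate = 0.2, p_perceive = 0)
  sim0 <- simulate_trial(cfg0, seed = 11)
  expect_length(sim0$truth$press_times, 0)

  cfg1 <- sim_config(trial_duration = 60, event_rate = 0.2, p_perceive = 1,
                     reaction_delay_mean = 0, reaction_delay_sd = 0)
  sim1 <- simulate_trial(cfg1, seed = 11)
  onsets <- sim1$truth$event_onsets
  expect_equal(sort(sim1$truth$press_times),
               sort(onsets[onsets <= cfg1$trial_duration]))
})

test_that("event process matches its Poisson mean rate", {
  cfg <- sim_config(trial_duration = 600, event_rate = 1 / 60)
  counts <- vapply(1:1000, function(s) nrow(sample_fetal_events(cfg, s)), 0L)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 10), 3 * se + 0.15)  # + small clipping allowance
})

test_that("perception frequency calibrates to p_perceive over many trials", {
  cfg <- sim_config(trial_duration = 60, event_rate = 0.25)
  tot <- 0L; per <- 0L
  for (s in 1:60) {
    tr <- simulate_trial(cfg, seed = 7000 + s)
    tot <- tot + length(tr$truth$perceived)
    per <- per + sum(tr$truth$perceived)
  }
  phat <- per / tot
  expect_lt(abs(phat - cfg$p_perceive), 4 * sqrt(0.4 * 0.6 / tot))
})

test_that("rigid-body property: global angular rate identical across sensors", {
  cfg <- sim_config(trial_duration = 20, event_rate = 0, noise_sd_acc = 0,
                    noise_sd_gyr = 0, drift_scale = 0)
  tr <- simulate_trial(cfg, seed = 3)$trial
  glob <- lapply(1:5, function(s) tr$gyr[, , s] %*% t(tr$mounting[[s]]))
  for (s in 2:5) expect_lt(max(abs(glob[[s]] - glob[[1]])), 1e-9)
})

test_that("fetal events are local: samples outside supports are unaffected", {
  base <- sim_config(trial_duration = 60, event_rate = 0.3)
  off <- sim_config(trial_duration = 60, event_rate = 0)
  a <- simulate_trial(base, seed = 21)
  b <- simulate_trial(off, seed = 21)
  n <- dim(a$trial$acc)[1]
  mask <- rep(FALSE, n)
  fs <- base$fs
  for (e in seq_along(a$truth$event_onsets)) {
    i0 <- floor(a$truth$event_onsets[e] * fs) + 1L
    i1 <- min(n, ceiling((a$truth$event_onsets[e] + a$truth$event_durations[e]) * fs) + 1L)
    mask[i0:i1] <- TRUE
  }
  expect_gt(sum(!mask), 0)
  expect_identical(a$trial$acc[!mask, , ], b$trial$acc[!mask, , ])
  expect_identical(a$trial$gyr[!mask, , ], b$trial$gyr[!mask, , ])
  # and the chest reference never receives any burst at all
  expect_identical(a$trial$acc[, , 5], b$trial$acc[, , 5])
  expect_false(any(vapply(a$truth$event_sensors, function(s) 5L %in% s, TRUE)))
})

test_that("calibration geometry: gravity and hinge axis appear as designed", {
  cfg <- quiet_config()
  cal <- simulate_calibration(cfg, seed = 2)
  ph <- cal$phases
  stat <- ph[ph$phase == "static", ]
  acc_mean <- colMeans(cal$acc[stat$start_sample:stat$end_sample, , 1])
  expect_equal(acc_mean, c(9.81, 0, 0), tolerance = 1e-8)

  # known mounting: 30 degrees about sensor z
  R30 <- fmdetect:::rotation_about_axis(c(0, 0, 1), 30 * pi / 180)
  cfg30 <- sim_config(trial_duration = 20, event_rate = 0, noise_sd_acc = 0,
                      noise_sd_gyr = 0, drift_scale = 0,
                      mounting_rotations = replicate(5, R30, simplify = FALSE))
  cal30 <- simulate_calibration(cfg30, seed = 2)
  acc_mean30 <- colMeans(cal30$acc[stat$start_sample:stat$end_sample, , 1])
  expect_equal(acc_mean30, as.numeric(t(R30) %*% c(9.81, 0, 0)), tolerance = 1e-8)

  # hinge principal axis is the frontal (y) axis under identity mounting
  hinge <- ph[ph$phase == "hinge1", ]
  g1 <- cal$gyr[hinge$start_sample:hinge$end_sample, , 1]
  ev <- eigen(crossprod(sweep(g1, 2, colMeans(g1))), symmetric = TRUE)
  cosang <- abs(sum(ev$vectors[, 1] * c(0, 1, 0)))
  expect_gt(cosang, 0.99)
  expect_equal(ph$phase, c("static", "hinge1", "hinge2", "hinge3"))
})

test_that("cohorts are deterministic and sized as requested", {
  cfg <- sim_config(trial_duration = 10, event_rate = 0.2)
  c1 <- make_cohort(3, cfg, seed = 9)
  c2 <- make_cohort(3, cfg, seed = 9)
  expect_identical(c1, c2)
  expect_length(make_cohort(1, cfg, seed = 1), 1L)
  # distinct trials within a cohort
  expect_false(identical(c1[[1]]$trial$acc, c1[[2]]$trial$acc))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(event_band = c(10, 100)), "Nyquist")
  expect_error(sim_config(p_perceive = 1.4), "p_perceive")
  expect_error(simulate_trial(sim_config(trial_duration = 0.3), 1), "too short")
  bad_mount <- replicate(5, matrix(rnorm(9), 3), simplify = FALSE)
  expect_error(sim_config(mounting_rotations = bad_mount), "orthonormal")
})
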