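test_that("presses become [-3.5, +1.5] s intervals", {
  ev <- presses_to_events(10)
  expect_equal(ev$start, 6.5)
  expect_equal(ev$end, 11.5)
  expect_equal(nrow(presses_to_events(numeric(0))), 0L)
  ev2 <- presses_to_events(c(10, 11))
  expect_equal(ev2$start, c(6.5, 7.5))
  # union length of the two overlapping intervals is 6 s
  mask <- fmdetect:::event_sample_mask(ev2, 20 * 128, 128)
  expect_equal(sum(mask) / 128, 6)
})

test_that("window grids follow floor arithmetic", {
  expect_equal(nrow(segment_windows(600 * 128, 0.5, 0.5, 128)), 1200L)
  expect_equal(nrow(segment_windows(600 * 128, 8, 1, 128)), 593L)
  expect_equal(nrow(segment_windows(64, 0.5, 0.5, 128)), 1L)
  expect_error(segment_windows(600 * 128, 0.5, 0, 128), "stride")
  expect_error(segment_windows(64, 8, 1, 128), "exceeds")
})

test_that("an isolated press labels exactly ten 0.5 s windows", {
  grid <- segment_windows(600 * 128, 0.5, 0.5, 128)
  lab <- label_windows(grid, presses_to_events(10))
  expect_equal(sum(lab), 10L)
  expect_equal(grid$grid_index[lab == 1], 13:22)
  expect_equal(sum(label_windows(grid, presses_to_events(numeric(0)))), 0L)
})

test_that("overlap boundary cases follow the strict >10% rule", {
  grid <- segment_windows(20 * 128, 0.5, 0.5, 128)
  ev <- presses_to_events(10)  # event [6.5, 11.5]
  lab <- label_windows(grid, ev)
  # window [6.0, 6.5) has zero overlap -> 0
  expect_equal(lab[grid$start_s == 6.0], 0L)
  # window [6.5, 7.0) fully inside -> 1
  expect_equal(lab[grid$start_s == 6.5], 1L)
  # overlap of exactly 10% is NOT enough (strictly greater than)
  # event [9.95, 25] overlaps window [9.5, 10) by exactly 0.05 s
  ev2 <- data.frame(start = 9.95, end = 15)
  lab2 <- label_windows(grid, ev2)
  expect_equal(lab2[grid$start_s == 9.5], 0L)
  # a hair more than 10% flips it
  ev3 <- data.frame(start = 9.9375, end = 15)   # 0.0625 s = 8 samples
  lab3 <- label_windows(grid, ev3)
  expect_equal(lab3[grid$start_s == 9.5], 1L)
})

test_that("labeling matches the brute-force per-sample oracle", {
  fs <- 128
  grid05 <- segment_windows(60 * fs, 0.5, 0.5, fs)
  grid8 <- segment_windows(60 * fs, 8, 1, fs)
  set.seed(42)
  ok <- vapply(1:200, function(i) {
    ev <- presses_to_events(runif(rpois(1, 3), 0, 60))
    identical(label_windows(grid05, ev), oracle_labels(grid05, ev)) &&
      identical(label_windows(grid8, ev), oracle_labels(grid8, ev))
  }, logical(1))
  expect_true(all(ok))
})

test_that("lowering the overlap threshold never removes positives", {
  fs <- 128
  grid <- segment_windows(60 * fs, 0.5, 0.5, fs)
  set.seed(7)
  for (i in 1:20) {
    ev <- presses_to_events(runif(3, 0, 60))
    hi <- label_windows(grid, ev, overlap_frac = 0.4)
    lo <- label_windows(grid, ev, overlap_frac = 0.05)
    expect_true(all(lo[hi == 1] == 1))
  }
})

test_that("rebalancing drops the stated number of negatives and no positives", {
  labels <- c(rep(1L, 44), rep(0L, 356))
  keep <- rebalance_training(labels, 2 / 3, seed = 1)
  expect_equal(sum(labels[keep] == 1), 44)
  expect_equal(sum(labels[keep] == 0), 356 - round(2 / 3 * 356))  # 119
  expect_identical(rebalance_training(labels, 0, seed = 1), seq_along(labels))
  expect_identical(rebalance_training(labels, 2 / 3, seed = 5),
                   rebalance_training(labels, 2 / 3, seed = 5))
  expect_warning(out <- rebalance_training(rep(0L, 10), 2 / 3, seed = 1),
                 "no positive")
  expect_identical(out, 1:10)
})

test_that("rebalancing an 11%-positive set yields about 27% positives", {
  n <- 10000
  labels <- c(rep(1L, 1100), rep(0L, 8900))
  keep <- rebalance_training(labels, 2 / 3, seed = 3)
  frac <- mean(labels[keep])
  closed_form <- 0.11 / (0.11 + 0.89 / 3)
  expect_equal(frac, closed_form, tolerance = 1e-3)
})
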