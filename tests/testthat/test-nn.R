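# Finite-difference gradient checks pin the analytic backpropagation of
# every layer at tiny sizes.

numeric_vs_analytic <- function(params, loss_fn, grads, n_probe = 6L) {
  eps <- 1e-6
  worst <- 0
  for (k in names(params)) {
    pk <- params[[k]]
    for (i in sample(length(pk), min(n_probe, length(pk)))) {
      p1 <- params; p1[[k]][i] <- p1[[k]][i] + eps
      p2 <- params; p2[[k]][i] <- p2[[k]][i] - eps
      num <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
      an <- grads[[k]][i]
      worst <- max(worst, abs(num - an) / max(1e-8, abs(num) + abs(an)))
    }
  }
  worst
}

test_that("BiLSTM backpropagation matches finite differences", {
  set.seed(42)
  B <- 3L; T <- 5L; C <- 2L; H <- 4L
  x <- array(rnorm(B * T * C), dim = c(B, T, C))
  y <- c(0, 1, 1)
  params <- c(fmdetect:::prefix_names(fmdetect:::lstm_init(C, H), "f_"),
              fmdetect:::prefix_names(fmdetect:::lstm_init(C, H), "b_"),
              list(W_out = fmdetect:::glorot_uniform(c(2 * H, 1), 2 * H, 1),
                   b_out = 0))
  loss_fn <- function(p)
    fmdetect:::bce_loss(fmdetect:::bilstm_forward(x, p, NULL, NULL, NULL)$p, y)
  fwd <- fmdetect:::bilstm_forward(x, params, NULL, NULL, NULL)
  gr <- fmdetect:::bilstm_backward(fwd, y, params)
  expect_lt(numeric_vs_analytic(params, loss_fn, gr), 1e-4)
})

test_that("CNN backpropagation matches finite differences", {
  set.seed(7)
  B <- 2L; bins <- 9L; frames <- 20L; C <- 2L
  x <- array(rnorm(bins * frames * C * B), dim = c(bins, frames, C, B))
  y <- c(0, 1)
  params <- fmdetect:::cnn_init(c(bins, frames, C), 4L, 3L, 5L)
  loss_fn <- function(p)
    fmdetect:::bce_loss(fmdetect:::cnn_forward(x, p, NULL, single = FALSE)$p, y)
  fwd <- fmdetect:::cnn_forward(x, params, NULL, single = FALSE)
  gr <- fmdetect:::cnn_backward(fwd, y, params)
  expect_lt(numeric_vs_analytic(params, loss_fn, gr, n_probe = 8L), 1e-4)
})

test_that("single-precision convolution kernels agree with the reference", {
  set.seed(19)
  x <- array(rnorm(9 * 40 * 3 * 2), dim = c(9, 40, 3, 2))
  w <- array(rnorm(3 * 3 * 3 * 8), dim = c(3, 3, 3, 8))
  b <- rnorm(8)
  f64 <- fmdetect:::.conv2d_fwd(x, w, b)
  f32 <- fmdetect:::.conv2d_fwd_f32(x, w, b)
  expect_equal(f32, f64, tolerance = 1e-5)
  dout <- array(rnorm(length(f64)), dim = dim(f64))
  b64 <- fmdetect:::.conv2d_bwd(x, w, dout, TRUE)
  b32 <- fmdetect:::.conv2d_bwd_f32(x, w, dout, TRUE)
  expect_equal(b32$dx, b64$dx, tolerance = 1e-4)
  expect_equal(b32$dw, b64$dw, tolerance = 1e-4)
  expect_equal(b32$db, b64$db, tolerance = 1e-4)
})

test_that("the compiled convolution agrees with a naive R triple loop", {
  set.seed(11)
  x <- array(rnorm(6 * 8 * 3 * 2), dim = c(6, 8, 3, 2))
  w <- array(rnorm(3 * 3 * 3 * 4), dim = c(3, 3, 3, 4))
  b <- rnorm(4)
  out <- fmdetect:::.conv2d_fwd(x, w, b)
  expect_equal(dim(out), c(4L, 6L, 4L, 2L))
  for (s in 1:2) for (f in 1:4) {
    naive <- matrix(0, 4, 6)
    for (i in 1:4) for (j in 1:6)
      naive[i, j] <- sum(x[i:(i + 2), j:(j + 2), , s] * w[, , , f]) + b[f]
    expect_equal(out[, , f, s], naive, tolerance = 1e-12)
  }
})

test_that("max pooling halves dimensions and routes gradients to the argmax", {
  x <- array(0, dim = c(4, 6, 1, 1))
  x[, , 1, 1] <- matrix(1:24, 4, 6)
  pl <- fmdetect:::.maxpool2_fwd(x)
  expect_equal(dim(pl$out), c(2L, 3L, 1L, 1L))
  expect_equal(pl$out[, , 1, 1], matrix(c(6, 8, 14, 16, 22, 24), 2, 3))
  dout <- pl$out * 0 + 1
  dx <- fmdetect:::.maxpool2_bwd(pl$argmax, dout, dim(x))
  expect_equal(sum(dx), 6)
  expect_equal(dx[2, 2, 1, 1], 1)  # position of the value 6
})

test_that("training is deterministic given the seed and scores stay in [0, 1]", {
  task <- easy_timeseries_task(60, seed = 1)
  val <- easy_timeseries_task(30, seed = 2)
  f1 <- train_bilstm(task$x, task$y, val$x, val$y, max_epochs = 2, seed = 5)
  f2 <- train_bilstm(task$x, task$y, val$x, val$y, max_epochs = 2, seed = 5)
  expect_identical(f1$params, f2$params)
  p <- predict(f1, val$x)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("an untrained network scores near-constant with chance AUROC", {
  task <- easy_timeseries_task(80, seed = 3)
  val <- easy_timeseries_task(20, seed = 4)
  f0 <- train_bilstm(task$x, task$y, val$x, val$y, max_epochs = 0, seed = 5)
  expect_equal(f0$epochs_trained, 0L)
  p <- predict(f0, task$x)
  expect_lt(sd(p), 0.1)
  expect_lt(abs(fmdetect:::auroc_rank(task$y, p) - 0.5), 0.25)
})

test_that("the CNN architecture has a fixed deterministic parameter count", {
  # 3x3x30x32 + 32 + 3x3x32x16 + 16 + 8016x16 + 16 + 16 + 1
  expected <- (3 * 3 * 30 * 32 + 32) + (3 * 3 * 32 * 16 + 16) +
    (501 * 16 * 16 + 16) + (16 + 1)
  expect_equal(cnn_param_count(30), expected)
  expect_equal(cnn_param_count(30), cnn_param_count(30))
  expect_equal(cnn_param_count(15),
               expected - 3 * 3 * 15 * 32)
})

test_that("shape mismatches are rejected", {
  task <- easy_spectrogram_task(12, seed = 5)
  fit <- train_cnn(task$x, task$y, task$x[1:4, , , , drop = FALSE], task$y[1:4],
                   max_epochs = 1, seed = 1)
  bad <- array(rnorm(2 * 9 * 500 * 1), dim = c(2, 9, 500, 1))
  expect_error(predict(fit, bad), "shape")
  badv <- array(rnorm(4 * 64 * 2), dim = c(4, 64, 2))
  tsk <- easy_timeseries_task(20, seed = 6)
  fitb <- train_bilstm(tsk$x, tsk$y, tsk$x[1:5, , ], tsk$y[1:5],
                       max_epochs = 1, seed = 1)
  expect_error(predict(fitb, badv), "shape")
})
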