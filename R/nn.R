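# Neural-network building blocks for the BiLSTM and CNN classifiers.
# These are compact reference implementations (batched forward passes,
# exact analytic gradients, Adam updates) written against base R matrix
# algebra and the package's compiled convolution kernels; gradient
# correctness is pinned by finite-difference tests.

sigmoid <- function(x) 1 / (1 + exp(-x))

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

glorot_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

# ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- LSTM (single direction) -----------------------------------------
# Gate order within the 4H blocks: input, forget, cell, output.
# X: [B, T, C]; returns the final hidden state h_T [B, H].
# recurrent_mask [B, H] implements variational recurrent dropout: the same
# mask multiplies h_{t-1} in the gate pre-activations at every timestep.

lstm_init <- function(input_dim, hidden) {
  Wx <- glorot_uniform(c(input_dim, 4L * hidden), input_dim, hidden)
  Wh <- glorot_uniform(c(hidden, 4L * hidden), hidden, hidden)
  b <- numeric(4L * hidden)
  b[(hidden + 1):(2 * hidden)] <- 1      # forget-gate bias
  list(Wx = Wx, Wh = Wh, b = b)
}

lstm_forward <- function(X, p, recurrent_mask = NULL) {
  d <- dim(X); B <- d[1]; T <- d[2]; H <- length(p$b) %/% 4L
  if (is.null(recurrent_mask)) recurrent_mask <- matrix(1, B, H)
  # input projections for every timestep in one GEMM: rows indexed (b, t)
  Xflat <- matrix(X, B * T, d[3])
  zx <- sweep(Xflat %*% p$Wx, 2L, p$b, "+")
  gates <- matrix(0, B * T, 4L * H)       # post-activation gates per step
  cs <- matrix(0, B * T, H); tc <- cs
  hprev <- matrix(0, B * T, H)            # (h_{t-1} * mask) rows per step
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  ii <- 1:H; fi <- (H + 1):(2 * H); gix <- (2 * H + 1):(3 * H); oi <- (3 * H + 1):(4 * H)
  for (t in seq_len(T)) {
    rows <- (t - 1L) * B + seq_len(B)
    hm <- h * recurrent_mask
    z <- zx[rows, , drop = FALSE] + hm %*% p$Wh
    i_g <- sigmoid(z[, ii, drop = FALSE])
    f_g <- sigmoid(z[, fi, drop = FALSE])
    g_g <- tanh(z[, gix, drop = FALSE])
    o_g <- sigmoid(z[, oi, drop = FALSE])
    cc <- f_g * cc + i_g * g_g
    tcc <- tanh(cc)
    h <- o_g * tcc
    gates[rows, ii] <- i_g; gates[rows, fi] <- f_g
    gates[rows, gix] <- g_g; gates[rows, oi] <- o_g
    cs[rows, ] <- cc; tc[rows, ] <- tcc; hprev[rows, ] <- hm
  }
  list(h = h,
       cache = list(Xflat = Xflat, d = d, gates = gates, cs = cs, tc = tc,
                    hprev = hprev, mask = recurrent_mask))
}

lstm_backward <- function(dh_last, cache, p) {
  d <- cache$d; B <- d[1]; T <- d[2]
  H <- ncol(dh_last)
  ii <- 1:H; fi <- (H + 1):(2 * H); gix <- (2 * H + 1):(3 * H); oi <- (3 * H + 1):(4 * H)
  dz_all <- matrix(0, B * T, 4L * H)
  dh <- dh_last
  dc <- matrix(0, B, H)
  mask <- cache$mask
  tWh <- t(p$Wh)
  for (t in seq.int(T, 1L)) {
    rows <- (t - 1L) * B + seq_len(B)
    i_g <- cache$gates[rows, ii, drop = FALSE]
    f_g <- cache$gates[rows, fi, drop = FALSE]
    g_g <- cache$gates[rows, gix, drop = FALSE]
    o_g <- cache$gates[rows, oi, drop = FALSE]
    tcc <- cache$tc[rows, , drop = FALSE]
    c_prev <- if (t > 1L) cache$cs[rows - B, , drop = FALSE] else matrix(0, B, H)
    do_g <- dh * tcc
    dc <- dc + dh * o_g * (1 - tcc^2)
    dz <- cbind((dc * g_g) * i_g * (1 - i_g),
                (dc * c_prev) * f_g * (1 - f_g),
                (dc * i_g) * (1 - g_g^2),
                do_g * o_g * (1 - o_g))
    dz_all[rows, ] <- dz
    dh <- (dz %*% tWh) * mask
    dc <- dc * f_g
  }
  dX <- array(dz_all %*% t(p$Wx), dim = d)
  list(Wx = crossprod(cache$Xflat, dz_all),
       Wh = crossprod(cache$hprev, dz_all),
       b = colSums(dz_all),
       dX = dX)
}

# ---- minibatch helper -------------------------------------------------

minibatch_indices <- function(n, batch_size) {
  ord <- sample.int(n)
  split(ord, ceiling(seq_along(ord) / batch_size))
}
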