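#' Train the bidirectional LSTM classifier on time-series windows
#'
#' A single bidirectional LSTM layer (64 units per direction by default)
#' regularized with dropout and variational recurrent dropout, followed by
#' a dense sigmoid head on the concatenated final states of both
#' directions.  Trained with Adam on binary cross-entropy, with early
#' stopping on validation loss.
#'
#' @param x Array `[n_windows, n_samples, channels]` of standardized
#'   training windows.
#' @param y Integer labels in {0, 1}.
#' @param val_x,val_y Validation windows and labels (required; early
#'   stopping monitors validation loss).
#' @param units LSTM units per direction (default 64).
#' @param dropout Dropout rate on the concatenated output state (0.3).
#' @param recurrent_dropout Variational dropout rate on the recurrent
#'   connections (0.3).
#' @param lr Adam learning rate (1e-3).
#' @param batch_size Minibatch size (64).
#' @param max_epochs Maximum training epochs (50); `0` returns the
#'   untrained network.
#' @param patience Early-stopping patience in epochs (5).
#' @param seed Integer seed for weight initialization, shuffling, and
#'   dropout masks; training is reproducible given the seed.
#' @param verbose Print per-epoch losses.
#' @return An object of class `fm_bilstm` with a [predict][predict.fm_bilstm]
#'   method returning scores in `[0, 1]`.
#' @export
train_bilstm <- function(x, y, val_x, val_y,
                         units = 64L, dropout = 0.3, recurrent_dropout = 0.3,
                         lr = 1e-3, batch_size = 64L, max_epochs = 50L,
                         patience = 5L, seed = 1L, verbose = FALSE) {
  d <- dim(x)
  if (length(d) != 3L) stop("x must be [n_windows, n_samples, channels]")
  if (length(y) != d[1]) stop("length(y) must match nrow(x)")
  if (missing(val_x) || is.null(val_x) || dim(val_x)[1] == 0L)
    stop("a non-empty validation set is required")
  if (any(dim(val_x)[-1] != d[-1])) stop("validation window shape mismatch")
  y <- as.numeric(y)

  set.seed(seed)
  params <- c(prefix_names(lstm_init(d[3], units), "f_"),
              prefix_names(lstm_init(d[3], units), "b_"),
              list(W_out = glorot_uniform(c(2L * units, 1L), 2L * units, 1L),
                   b_out = 0))
  state <- adam_init(params)

  best <- list(params = params, loss = Inf, epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(max_epochs)) {
    for (ids in minibatch_indices(d[1], batch_size)) {
      xb <- x[ids, , , drop = FALSE]
      yb <- y[ids]
      B <- length(ids)
      rmask_f <- dropout_mask(B, units, recurrent_dropout)
      rmask_b <- dropout_mask(B, units, recurrent_dropout)
      fwd <- bilstm_forward(xb, params, rmask_f, rmask_b,
                            drop_mask = dropout_mask(B, 2L * units, dropout))
      grads <- bilstm_backward(fwd, yb, params)
      upd <- adam_step(params, grads, state, lr = lr)
      params <- upd$params; state <- upd$state
    }
    val_p <- bilstm_scores(val_x, params, batch_size)
    val_loss <- bce_loss(val_p, as.numeric(val_y))
    if (verbose) message(sprintf("epoch %d: val loss %.4f", epoch, val_loss))
    if (val_loss < best$loss - 1e-6) {
      best <- list(params = params, loss = val_loss, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  if (max_epochs == 0L) best$params <- params

  structure(list(params = best$params, units = units,
                 input_shape = d[-1], val_loss = best$loss,
                 epochs_trained = best$epoch, seed = seed,
                 batch_size = batch_size),
            class = "fm_bilstm")
}

prefix_names <- function(lst, prefix) {
  names(lst) <- paste0(prefix, names(lst))
  lst
}

dropout_mask <- function(nrow, ncol, rate) {
  if (rate <= 0) return(matrix(1, nrow, ncol))
  matrix((runif(nrow * ncol) >= rate) / (1 - rate), nrow, ncol)
}

bilstm_forward <- function(xb, params, rmask_f, rmask_b, drop_mask = NULL) {
  pf <- list(Wx = params$f_Wx, Wh = params$f_Wh, b = params$f_b)
  pb <- list(Wx = params$b_Wx, Wh = params$b_Wh, b = params$b_b)
  xb_rev <- xb[, rev(seq_len(dim(xb)[2])), , drop = FALSE]
  ff <- lstm_forward(xb, pf, rmask_f)
  fb <- lstm_forward(xb_rev, pb, rmask_b)
  h <- cbind(ff$h, fb$h)
  if (!is.null(drop_mask)) h_d <- h * drop_mask else {
    drop_mask <- matrix(1, nrow(h), ncol(h)); h_d <- h
  }
  logits <- h_d %*% params$W_out + params$b_out
  list(p = as.vector(sigmoid(logits)), h_d = h_d, drop_mask = drop_mask,
       ff = ff, fb = fb)
}

bilstm_backward <- function(fwd, yb, params) {
  B <- length(yb)
  units <- ncol(fwd$ff$h)
  dlogit <- matrix((fwd$p - yb) / B, ncol = 1L)
  dW_out <- crossprod(fwd$h_d, dlogit)
  db_out <- sum(dlogit)
  dh <- (dlogit %*% t(params$W_out)) * fwd$drop_mask
  pf <- list(Wx = params$f_Wx, Wh = params$f_Wh, b = params$f_b)
  pb <- list(Wx = params$b_Wx, Wh = params$b_Wh, b = params$b_b)
  gf <- lstm_backward(dh[, seq_len(units), drop = FALSE], fwd$ff$cache, pf)
  gb <- lstm_backward(dh[, units + seq_len(units), drop = FALSE], fwd$fb$cache, pb)
  c(prefix_names(gf[c("Wx", "Wh", "b")], "f_"),
    prefix_names(gb[c("Wx", "Wh", "b")], "b_"),
    list(W_out = dW_out, b_out = db_out))
}

bilstm_scores <- function(x, params, batch_size = 256L) {
  n <- dim(x)[1]
  out <- numeric(n)
  for (ids in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    fwd <- bilstm_forward(x[ids, , , drop = FALSE], params,
                          rmask_f = NULL, rmask_b = NULL, drop_mask = NULL)
    out[ids] <- fwd$p
  }
  out
}

#' Predict fetal-movement scores from a fitted BiLSTM
#'
#' @param object An `fm_bilstm`.
#' @param newdata Array `[n_windows, n_samples, channels]`, standardized
#'   with the training-set statistics.
#' @param ... Unused.
#' @return Numeric scores in `[0, 1]`.
#' @export
predict.fm_bilstm <- function(object, newdata, ...) {
  if (any(dim(newdata)[-1] != object$input_shape))
    stop("newdata window shape does not match the fitted model")
  bilstm_scores(newdata, object$params)
}

#' @export
print.fm_bilstm <- function(x, ...) {
  cat(sprintf("BiLSTM classifier: %d units/direction, input %d x %d, %d epochs (best val loss %.4f)\n",
              x$units, x$input_shape[1], x$input_shape[2],
              x$epochs_trained, x$val_loss))
  invisible(x)
}
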