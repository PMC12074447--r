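#' Train the spectrogram CNN classifier
#'
#' The architecture: a 2-D convolutional layer with 32 filters of size
#' (3, 3) and ReLU activation; a (2, 2) max-pooling layer; a second
#' convolutional layer with 16 filters of size (3, 3) and ReLU; flatten; a
#' dense layer with 16 units and ReLU; dropout with rate 0.25; and a final
#' sigmoid unit.  Trained with Adam on binary cross-entropy with early
#' stopping on validation loss.
#'
#' @param x Training spectrogram windows: either a numeric array
#'   `[n_windows, bins, frames, channels]` or a lazy window set from
#'   [spec_window_set()] (which slices windows out of trial-level
#'   spectrograms on demand, saving memory).
#' @param y Integer labels in {0, 1}.
#' @param val_x,val_y Validation windows and labels (required).
#' @param filters1,filters2 Filter counts of the two convolutional layers
#'   (defaults 32 and 16).
#' @param dense_units Units of the dense layer (16).
#' @param dropout Dropout rate before the output layer (0.25).
#' @param lr Adam learning rate (1e-3).
#' @param batch_size Minibatch size (64).
#' @param max_epochs Maximum epochs (50); `0` returns the untrained
#'   network.
#' @param patience Early-stopping patience (5).
#' @param restarts Number of independent training runs.  With
#'   `restarts > 1` the fitted model is a small deep ensemble: every run
#'   is kept and prediction averages the member scores, which is far more
#'   robust than any single trajectory when the training set is small.
#'   `lr` may be a vector, in which case runs cycle through it.
#' @param seed Integer seed; training is reproducible given the seed.
#' @param precision `"single"` (default) runs the convolutions in float32,
#'   standard practice for network training; `"double"` uses the
#'   double-precision reference kernels.
#' @param verbose Print per-epoch losses.
#' @return An object of class `fm_cnn` with a [predict][predict.fm_cnn]
#'   method returning scores in `[0, 1]`.
#' @export
train_cnn <- function(x, y, val_x, val_y,
                      filters1 = 32L, filters2 = 16L, dense_units = 16L,
                      dropout = 0.25, lr = 1e-3, batch_size = 64L,
                      max_epochs = 50L, patience = 5L, restarts = 1L,
                      seed = 1L, precision = c("single", "double"),
                      verbose = FALSE) {
  precision <- match.arg(precision)
  single <- precision == "single"
  if (restarts > 1L || length(lr) > 1L) {
    restarts <- max(restarts, length(lr))
    fits <- lapply(seq_len(restarts), function(r)
      train_cnn(x, y, val_x, val_y, filters1 = filters1,
                filters2 = filters2, dense_units = dense_units,
                dropout = dropout, lr = lr[(r - 1L) %% length(lr) + 1L],
                batch_size = batch_size,
                max_epochs = max_epochs, patience = patience, restarts = 1L,
                seed = derive_seed(seed, 40L + r), precision = precision,
                verbose = verbose))
    ens <- fits[[1L]]
    ens$members <- lapply(fits, function(f) f$params)
    ens$member_val_auroc <- vapply(fits, function(f) f$val_auroc, 0)
    ens$val_auroc <- mean(ens$member_val_auroc)
    ens$restarts <- restarts
    return(ens)
  }
  x <- as_spec_source(x)
  val_x <- as_spec_source(val_x)
  if (x$n == 0L) stop("empty training set")
  if (val_x$n == 0L) stop("a non-empty validation set is required")
  if (any(x$shape != val_x$shape)) stop("validation spectrogram shape mismatch")
  if (length(y) != x$n) stop("length(y) must match the number of windows")
  y <- as.numeric(y)

  set.seed(seed)
  params <- cnn_init(x$shape, filters1, filters2, dense_units)
  state <- adam_init(params)

  best <- list(params = params, loss = Inf, epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(max_epochs)) {
    for (ids in minibatch_indices(x$n, batch_size)) {
      xb <- x$fetch(ids)
      B <- length(ids)
      fwd <- cnn_forward(xb, params,
                         drop_mask = dropout_mask(B, dense_units, dropout),
                         single = single, cache = single)
      grads <- cnn_backward(fwd, y[ids], params)
      upd <- adam_step(params, grads, state, lr = lr)
      params <- upd$params; state <- upd$state
    }
    val_p <- cnn_scores(val_x, params, batch_size, single = single)
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

  val_auroc <- auroc_rank(as.numeric(val_y),
                          cnn_scores(val_x, best$params, batch_size,
                                     single = single))
  structure(list(params = best$params, input_shape = x$shape,
                 val_loss = best$loss, val_auroc = val_auroc,
                 epochs_trained = best$epoch,
                 precision = precision, seed = seed), class = "fm_cnn")
}

cnn_init <- function(shape, filters1, filters2, dense_units) {
  bins <- shape[1]; frames <- shape[2]; channels <- shape[3]
  h2 <- (bins - 2L) %/% 2L; w2 <- (frames - 2L) %/% 2L
  flat_dim <- (h2 - 2L) * (w2 - 2L) * filters2
  if (flat_dim <= 0) stop("input spectrogram too small for the architecture")
  list(
    W1 = glorot_uniform(c(3L, 3L, channels, filters1), 9L * channels, 9L * filters1),
    b1 = numeric(filters1),
    W2 = glorot_uniform(c(3L, 3L, filters1, filters2), 9L * filters1, 9L * filters2),
    b2 = numeric(filters2),
    W3 = glorot_uniform(c(flat_dim, dense_units), flat_dim, dense_units),
    b3 = numeric(dense_units),
    W4 = glorot_uniform(c(dense_units, 1L), dense_units, 1L),
    b4 = 0
  )
}

#' Parameter count of the CNN architecture
#'
#' A fixed, deterministic function of the input shape; useful for checking
#' architecture determinism.
#'
#' @param channels Input channels (15 single modality, 30 combined).
#' @param bins,frames Spectrogram dimensions (9 and 1009 for 8 s at
#'   128 Hz).
#' @return Integer number of trainable parameters.
#' @export
cnn_param_count <- function(channels, bins = 9L, frames = 1009L) {
  p <- cnn_init(c(bins, frames, channels), 32L, 16L, 16L)
  sum(vapply(p, length, 0L))
}

# `cache = TRUE` (training path, float32 only) keeps the im2col patch
# matrices from the forward pass so the backward pass reuses them.
cnn_forward <- function(xb, params, drop_mask = NULL, single = TRUE,
                        cache = FALSE) {
  B <- dim(xb)[4]
  c1 <- NULL; c2 <- NULL
  if (single && cache) {
    f1 <- .conv2d_fwd_f32c(xb, params$W1, params$b1)
    a1 <- f1$out; c1 <- f1$cache
  } else {
    a1 <- if (single) .conv2d_fwd_f32(xb, params$W1, params$b1) else
      .conv2d_fwd(xb, params$W1, params$b1)
  }
  r1 <- pmax(a1, 0); dim(r1) <- dim(a1)
  pl <- .maxpool2_fwd(r1)
  if (single && cache) {
    f2 <- .conv2d_fwd_f32c(pl$out, params$W2, params$b2)
    a2 <- f2$out; c2 <- f2$cache
  } else {
    a2 <- if (single) .conv2d_fwd_f32(pl$out, params$W2, params$b2) else
      .conv2d_fwd(pl$out, params$W2, params$b2)
  }
  r2 <- pmax(a2, 0)
  flat <- matrix(r2, ncol = B)          # [flat_dim, B], column-major per sample
  a3 <- sweep(crossprod(flat, params$W3), 2L, params$b3, "+")
  r3 <- pmax(a3, 0)
  if (is.null(drop_mask)) drop_mask <- matrix(1, B, ncol(r3))
  h <- r3 * drop_mask
  logits <- h %*% params$W4 + params$b4
  list(p = as.vector(sigmoid(logits)), xb = xb, a1 = a1, r1 = r1, pl = pl,
       a2 = a2, flat = flat, a3 = a3, h = h, drop_mask = drop_mask,
       single = single, c1 = c1, c2 = c2)
}

cnn_backward <- function(fwd, yb, params) {
  B <- length(yb)
  dlogit <- matrix((fwd$p - yb) / B, ncol = 1L)
  dW4 <- crossprod(fwd$h, dlogit)
  db4 <- sum(dlogit)
  dh <- (dlogit %*% t(params$W4)) * fwd$drop_mask
  da3 <- dh * (fwd$a3 > 0)
  dW3 <- fwd$flat %*% da3
  db3 <- colSums(da3)
  dflat <- params$W3 %*% t(da3)         # [flat_dim, B]
  dr2 <- array(as.vector(dflat), dim = dim(fwd$a2)) * (fwd$a2 > 0)
  if (!is.null(fwd$c2)) {
    bwd2 <- .conv2d_bwd_f32c(fwd$c2, params$W2, dr2, TRUE)
  } else if (isTRUE(fwd$single)) {
    bwd2 <- .conv2d_bwd_f32(fwd$pl$out, params$W2, dr2, TRUE)
  } else {
    bwd2 <- .conv2d_bwd(fwd$pl$out, params$W2, dr2, TRUE)
  }
  dpool <- .maxpool2_bwd(fwd$pl$argmax, bwd2$dx, dim(fwd$r1))
  dr1 <- dpool * (fwd$a1 > 0)
  if (!is.null(fwd$c1)) {
    bwd1 <- .conv2d_bwd_f32c(fwd$c1, params$W1, dr1, FALSE)
  } else if (isTRUE(fwd$single)) {
    bwd1 <- .conv2d_bwd_f32(fwd$xb, params$W1, dr1, FALSE)
  } else {
    bwd1 <- .conv2d_bwd(fwd$xb, params$W1, dr1, FALSE)
  }
  list(W1 = bwd1$dw, b1 = bwd1$db, W2 = bwd2$dw, b2 = bwd2$db,
       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4)
}

cnn_scores <- function(x, params, batch_size = 64L, single = TRUE) {
  x <- as_spec_source(x)
  out <- numeric(x$n)
  for (ids in split(seq_len(x$n), ceiling(seq_len(x$n) / batch_size))) {
    fwd <- cnn_forward(x$fetch(ids), params, drop_mask = NULL, single = single)
    out[ids] <- fwd$p
  }
  out
}

# Mean score over ensemble members (a single fit has no members field).
cnn_model_scores <- function(object, src) {
  single <- identical(object$precision %||% "single", "single")
  if (is.null(object$members))
    return(cnn_scores(src, object$params, single = single))
  rowMeans(vapply(object$members, function(p)
    cnn_scores(src, p, single = single), numeric(src$n)))
}

#' Predict fetal-movement scores from a fitted CNN
#'
#' @param object An `fm_cnn`.
#' @param newdata Spectrogram windows (array `[n, bins, frames, channels]`
#'   or a [spec_window_set()]), normalized with training statistics.
#' @param ... Unused.
#' @return Numeric scores in `[0, 1]`.
#' @export
predict.fm_cnn <- function(object, newdata, ...) {
  src <- as_spec_source(newdata)
  if (any(src$shape != object$input_shape))
    stop(sprintf("spectrogram shape (%s) does not match the fitted model (%s)",
                 paste(src$shape, collapse = "x"),
                 paste(object$input_shape, collapse = "x")))
  cnn_model_scores(object, src)
}

#' @export
print.fm_cnn <- function(x, ...) {
  cat(sprintf("Spectrogram CNN: input %s, %d parameters, %d epochs (best val loss %.4f)\n",
              paste(x$input_shape, collapse = "x"),
              sum(vapply(x$params, length, 0L)),
              x$epochs_trained, x$val_loss))
  invisible(x)
}

# ---- spectrogram window sources --------------------------------------

#' Lazy spectrogram window set
#'
#' Wraps trial-level spectrograms so that per-window stacks are sliced out
#' on demand (the stride-1 STFT makes every 8 s window an exact contiguous
#' frame block), avoiding materializing all windows at once.
#'
#' @param trial_specs List of trial-level spectrograms from
#'   [trial_spectrogram()].
#' @param trial Integer index into `trial_specs` per window.
#' @param frame0 First trial frame (1-based) of each window.
#' @param n_frames Frames per window (1009 for 8 s at 128 Hz).
#' @param scale Optional divisor from training statistics: either a
#'   per-channel vector (max-magnitude normalization) or a
#'   `bins x channels` matrix (per-bin standardization).
#' @param center Optional `bins x channels` matrix subtracted before
#'   scaling (per-bin mean from training statistics).
#' @return An object of class `fm_spec_windows`.
#' @export
spec_window_set <- function(trial_specs, trial, frame0, n_frames = 1009L,
                            scale = NULL, center = NULL) {
  stopifnot(length(trial) == length(frame0))
  structure(list(trial_specs = trial_specs, trial = trial, frame0 = frame0,
                 n_frames = as.integer(n_frames), scale = scale,
                 center = center),
            class = "fm_spec_windows")
}

as_spec_source <- function(x) {
  if (inherits(x, "fm_spec_windows")) {
    d1 <- dim(x$trial_specs[[1]])
    shape <- c(d1[1], x$n_frames, d1[3])
    scale <- x$scale
    fetch <- function(ids) {
      out <- array(0, dim = c(shape, length(ids)))
      for (j in seq_along(ids)) {
        i <- ids[j]
        blk <- x$trial_specs[[x$trial[i]]][, x$frame0[i]:(x$frame0[i] + x$n_frames - 1L), , drop = FALSE]
        out[, , , j] <- blk
      }
      if (!is.null(x$center)) {
        for (c in seq_len(shape[3])) out[, , c, ] <- out[, , c, ] - x$center[, c]
      }
      if (!is.null(scale)) {
        if (is.matrix(scale)) {
          for (c in seq_len(shape[3])) out[, , c, ] <- out[, , c, ] / scale[, c]
        } else {
          for (c in seq_len(shape[3])) out[, , c, ] <- out[, , c, ] / scale[c]
        }
      }
      out
    }
    return(list(n = length(x$trial), shape = shape, fetch = fetch))
  }
  if (is.list(x) && !is.null(x$fetch)) return(x)
  d <- dim(x)
  if (length(d) != 4L)
    stop("spectrogram windows must be [n, bins, frames, channels]")
  list(n = d[1], shape = d[-1],
       fetch = function(ids) aperm(x[ids, , , , drop = FALSE], c(2, 3, 4, 1)))
}
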