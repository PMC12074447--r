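#' Train the random forest classifier on hand-engineered features
#'
#' Fits a random forest to the 75-per-modality feature vectors, with
#' hyperparameters chosen by random search: `search_budget` configurations
#' are drawn (number of trees 100--500, maximum depth unlimited or 5--30,
#' minimum node size 2--10, features per split sqrt or log2), each is
#' fitted on the training set, and the configuration maximizing F1 on the
#' validation set (threshold 0.5) is retained.  Scores are the fraction of
#' trees voting positive, matching majority-vote aggregation.
#'
#' @param x Numeric feature matrix (training windows).
#' @param y Integer labels in {0, 1}; both classes must be present.
#' @param val_x,val_y Validation features and labels, disjoint from
#'   training at the trial level.
#' @param search_budget Number of random hyperparameter draws (default 25).
#' @param seed Integer seed; the search and the forests are reproducible.
#' @return An object of class `fm_rf` with a [predict][predict.fm_rf]
#'   method returning vote fractions in `[0, 1]`.
#' @export
train_rf <- function(x, y, val_x, val_y, search_budget = 25L, seed = 1L) {
  if (!all(is.finite(x))) stop("features must be finite")
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class; cannot fit a classifier")
  y <- factor(y, levels = c(0L, 1L))
  val_y <- as.integer(as.character(val_y))
  df <- as.data.frame(x)
  val_df <- as.data.frame(val_x)
  colnames(val_df) <- colnames(df)

  set.seed(seed)
  draws <- data.frame(
    num_trees = sample(seq.int(100L, 500L), search_budget, replace = TRUE),
    max_depth = sample(c(0L, seq.int(5L, 30L)), search_budget, replace = TRUE),
    min_node = sample(seq.int(2L, 10L), search_budget, replace = TRUE),
    mtry_rule = sample(c("sqrt", "log2"), search_budget, replace = TRUE),
    fit_seed = sample.int(1e6, search_budget)
  )
  p <- ncol(df)
  best <- list(f1 = -Inf)
  for (i in seq_len(search_budget)) {
    mtry <- max(1L, if (draws$mtry_rule[i] == "sqrt") floor(sqrt(p)) else floor(log2(p)))
    fit <- ranger::ranger(
      x = df, y = y, num.trees = draws$num_trees[i],
      max.depth = draws$max_depth[i], min.node.size = draws$min_node[i],
      mtry = mtry, seed = draws$fit_seed[i], num.threads = 1L,
      verbose = FALSE)
    scores <- rf_vote_fraction(fit, val_df)
    pred <- as.integer(scores >= 0.5)
    f1 <- f1_score(val_y, pred)
    if (f1 > best$f1) best <- list(f1 = f1, fit = fit, config = draws[i, ])
  }
  structure(list(forest = best$fit, val_f1 = best$f1,
                 config = best$config, feature_names = colnames(df),
                 seed = seed),
            class = "fm_rf")
}

f1_score <- function(y, pred) {
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  if (tp == 0L) return(0)
  ppv <- tp / (tp + fp)
  sens <- tp / (tp + fn)
  2 * ppv * sens / (ppv + sens)
}

# Fraction of trees voting for the positive class, per window.
rf_vote_fraction <- function(forest, df) {
  votes <- predict(forest, data = df, predict.all = TRUE,
                   num.threads = 1L)$predictions
  # ranger codes classes by factor level index: 1 = "0", 2 = "1"
  rowMeans(votes == 2L)
}

#' Predict fetal-movement vote fractions from a fitted random forest
#'
#' @param object An `fm_rf`.
#' @param newdata Feature matrix with the training columns.
#' @param ... Unused.
#' @return Numeric scores in `[0, 1]` (fraction of trees voting positive).
#' @export
predict.fm_rf <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  colnames(df) <- object$feature_names
  rf_vote_fraction(object$forest, df)
}

#' @export
print.fm_rf <- function(x, ...) {
  cat(sprintf("Random forest classifier: %d trees, depth %s, val F1 %.3f\n",
              x$config$num_trees,
              if (x$config$max_depth == 0) "unlimited" else x$config$max_depth,
              x$val_f1))
  invisible(x)
}

#' Threshold scores into binary labels
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param threshold Decision threshold in (0, 1); a window is positive
#'   when its score is at least the threshold, so the predicted-positive
#'   set shrinks monotonically as the threshold rises.
#' @return Integer labels in {0, 1}.
#' @export
classify <- function(scores, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  as.integer(scores >= threshold)
}
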