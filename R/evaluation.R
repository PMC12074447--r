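#' Pre-select Monte Carlo cross-validation splits
#'
#' Draws `n_splits` independent trial-level splits: `n_test` trials for
#' testing, `n_val` for validation, the remainder for training, sampled
#' without replacement within each split.  Splits are pre-selected before
#' any training and reused identically for every data representation, so
#' model comparisons are paired.
#'
#' @param trial_ids Vector of trial identifiers (the study default is 49
#'   trials with 6 test / 6 validation / 37 training).
#' @param n_splits Number of Monte Carlo splits (default 10).
#' @param n_test,n_val Trials per test and validation set (defaults 6, 6).
#' @param seed Integer seed; the plan is deterministic.
#' @return A list of class `fm_split_plan`; each element has `split_id`,
#'   `test`, `validation`, `train`.
#' @export
make_splits <- function(trial_ids, n_splits = 10L, n_test = 6L, n_val = 6L,
                        seed = 1L) {
  n <- length(trial_ids)
  if (n < n_test + n_val + 1L)
    stop(sprintf("too few trials: need at least %d, got %d", n_test + n_val + 1L, n))
  set.seed(seed)
  plans <- lapply(seq_len(n_splits), function(k) {
    held <- sample(trial_ids, n_test + n_val)
    list(split_id = k,
         test = held[seq_len(n_test)],
         validation = held[n_test + seq_len(n_val)],
         train = setdiff(trial_ids, held))
  })
  structure(plans, class = "fm_split_plan")
}

#' Compute the detection metrics for one scored window set
#'
#' Accuracy, sensitivity, specificity, positive predictive value, F1, and
#' AUROC, plus the confusion counts.  AUROC is threshold-free, computed
#' from the Mann-Whitney rank statistic with midrank tie handling; the
#' thresholded metrics use [classify()] at `threshold`.  Ratios with a
#' zero denominator are reported as 0 and flagged in `$undefined`.
#'
#' @param labels Integer labels in {0, 1}.
#' @param scores Numeric scores in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return An object of class `fm_metrics`: a list with `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`, `f1`, `auroc`, `confusion`
#'   (tp/fp/fn/tn), `threshold`, `n`, and `undefined` (names of flagged
#'   metrics).
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  if (length(labels) == 0L) stop("empty input")
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  pred <- classify(scores, threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(0) }
    num / den
  }
  sens <- ratio(tp, tp + fn, "sensitivity")
  spec <- ratio(tn, tn + fp, "specificity")
  ppv <- ratio(tp, tp + fp, "ppv")
  f1 <- if (ppv + sens == 0) { undefined <- c(undefined, "f1"); 0 } else
    2 * ppv * sens / (ppv + sens)
  auroc <- auroc_rank(labels, scores)
  if (is.na(auroc)) { undefined <- c(undefined, "auroc"); auroc <- 0 }
  structure(list(
    accuracy = (tp + tn) / length(labels),
    sensitivity = sens, specificity = spec, ppv = ppv, f1 = f1,
    auroc = auroc,
    confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
    threshold = threshold, n = length(labels),
    undefined = undefined), class = "fm_metrics")
}

# AUROC via the Mann-Whitney rank-sum statistic with midranks for ties;
# equals the trapezoidal area under the empirical ROC curve.
auroc_rank <- function(labels, scores) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.fm_metrics <- function(x, ...) {
  cat(sprintf("Detection metrics (n = %d windows, threshold %.2f)\n", x$n, x$threshold))
  cat(sprintf("  accuracy %.3f  sensitivity %.3f  specificity %.3f\n",
              x$accuracy, x$sensitivity, x$specificity))
  cat(sprintf("  PPV %.3f  F1 %.3f  AUROC %.3f\n", x$ppv, x$f1, x$auroc))
  cm <- format_confusion(x)
  cat("  confusion (percent of total, count):\n")
  cat(sprintf("    TP %s  FN %s\n    FP %s  TN %s\n",
              cm["tp"], cm["fn"], cm["fp"], cm["tn"]))
  if (length(x$undefined))
    cat("  undefined (reported as 0):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Format a confusion matrix as percent-of-total with raw counts
#'
#' Each cell is rendered as the percentage of the total number of windows
#' with the raw count in parentheses, the format used to compare models
#' whose window sizes (and hence totals) differ.
#'
#' @param metrics An `fm_metrics` object.
#' @return Named character vector (`tp`, `fp`, `fn`, `tn`).
#' @export
format_confusion <- function(metrics) {
  stopifnot(inherits(metrics, "fm_metrics"))
  total <- sum(metrics$confusion)
  out <- sprintf("%.1f%% (%d)", 100 * metrics$confusion / total, metrics$confusion)
  names(out) <- names(metrics$confusion)
  out
}

#' Paired significance test across split-level metrics
#'
#' Two-sided paired-difference test over per-split metric values (paired
#' by split identifier).  The default is the paired t-test; the Wilcoxon
#' signed-rank test is available as an option.  If every difference is
#' zero the p-value is 1 by convention; if the differences are a non-zero
#' constant the p-value is reported as 0 (the paired t statistic
#' diverges).
#'
#' @param a,b Numeric vectors of equal length >= 2, one value per split.
#' @param method `"t"` (default) or `"wilcoxon"`.
#' @return The two-sided p-value.
#' @export
paired_test <- function(a, b, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("a and b must be paired (equal length)")
  if (length(a) < 2L) stop("need at least 2 paired values")
  d <- a - b
  if (all(d == 0)) return(1)
  if (sd(d) == 0) return(0)
  if (method == "t") {
    t.test(a, b, paired = TRUE)$p.value
  } else {
    suppressWarnings(wilcox.test(a, b, paired = TRUE)$p.value)
  }
}

#' Sweep the decision threshold
#'
#' Recomputes all metrics while varying the decision threshold from 0.1
#' to 0.9 in increments of 0.1 (by default).  Because the
#' predicted-positive set shrinks as the threshold rises, sensitivity is
#' non-increasing and specificity non-decreasing across the sweep.
#'
#' @param labels,scores As in [compute_metrics()].
#' @param thresholds Numeric vector of thresholds.
#' @return A data.frame with one row per threshold and columns
#'   `threshold`, `accuracy`, `sensitivity`, `specificity`, `ppv`, `f1`,
#'   `auroc`, `tp`, `fp`, `fn`, `tn`.
#' @export
threshold_sweep <- function(labels, scores, thresholds = seq(0.1, 0.9, by = 0.1)) {
  rows <- lapply(thresholds, function(th) {
    m <- compute_metrics(labels, scores, threshold = th)
    data.frame(threshold = th, accuracy = m$accuracy,
               sensitivity = m$sensitivity, specificity = m$specificity,
               ppv = m$ppv, f1 = m$f1, auroc = m$auroc,
               tp = m$confusion["tp"], fp = m$confusion["fp"],
               fn = m$confusion["fn"], tn = m$confusion["tn"],
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Training-set-size sweep
#'
#' Evaluates a pipeline at a sequence of training-set fractions.  Training
#' trials are subsampled at the trial level (preserving subject-level
#' independence): a single random permutation of the training trials is
#' drawn, and each fraction uses its first `ceiling(fraction * n)`
#' elements, so smaller sets are nested in larger ones and fraction 1
#' reproduces the full run exactly.  Test sets are untouched, hence
#' identical across fractions.
#'
#' @param pipeline Function taking a vector of training trial ids and
#'   returning a named list or vector of metrics (e.g. a closure around
#'   [run_experiment()] internals or a custom fit/score routine).
#' @param train_trials Vector of available training trial ids.
#' @param fractions Fractions in (0, 1] (default 0.25, 0.5, 0.75, 1).
#' @param seed Integer seed for the subsampling permutation.
#' @return A data.frame with `fraction`, `n_train_trials`, and one column
#'   per metric returned by `pipeline`.
#' @export
training_size_sweep <- function(pipeline, train_trials,
                                fractions = c(0.25, 0.5, 0.75, 1),
                                seed = 1L) {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  set.seed(seed)
  perm <- sample(train_trials)
  rows <- lapply(fractions, function(f) {
    k <- ceiling(f * length(perm))
    if (k < 1L) stop("fraction yields zero training trials")
    sub <- if (f == 1) train_trials else perm[seq_len(k)]
    res <- pipeline(sub)
    cbind(data.frame(fraction = f, n_train_trials = length(sub)),
          as.data.frame(as.list(unlist(res))))
  })
  do.call(rbind, rows)
}
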