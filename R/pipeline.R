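#' Experiment configuration
#'
#' Bundles every stage's parameters for [run_experiment()].  Defaults are
#' the study protocol where it states a value (128 Hz sampling, 1--20 Hz
#' zero-phase bandpass, events from presses at [-3.5, +1.5] s, >10%
#' overlap labeling, 0.5 s non-overlapping windows for features and time
#' series, 8 s windows with 1 s stride for spectrograms, two-thirds
#' negative discard in training, 0.5 decision threshold); cohort size,
#' split counts, and network training epochs default to a desk-scale
#' demonstration size (see the package vignette for the rationale).
#'
#' @param n_trials Number of simulated trials in the cohort.
#' @param sim An [sim_config()].
#' @param filter An [filter_spec()].
#' @param n_splits,n_test,n_val Monte Carlo split plan parameters.
#' @param models Subset of `c("rf", "bilstm", "cnn")`.
#' @param modalities Subset of `c("acc", "gyr", "combined")`.
#' @param overlap_frac Window-labeling overlap fraction (0.1).
#' @param drop_fraction Fraction of training negatives discarded (2/3).
#' @param threshold Decision threshold for the reported metrics (0.5).
#' @param rf_search_budget Random-search draws for the random forest.
#' @param bilstm,cnn Named lists of overrides passed to [train_bilstm()] /
#'   [train_cnn()] (e.g. `max_epochs`, `batch_size`).
#' @param seed Master seed; every stage derives its randomness from it.
#' @param keep_scores Keep per-window test scores in the result (needed
#'   for threshold sweeps on the result object).
#' @param out_dir Optional directory; when set, labels, split plans, and
#'   metrics are written there with a configuration-hash provenance stamp.
#' @return An object of class `fm_experiment_config`.
#' @export
experiment_config <- function(n_trials = 8L,
                              sim = sim_config(trial_duration = 120),
                              filter = filter_spec(),
                              n_splits = 1L, n_test = 2L, n_val = 2L,
                              models = c("rf", "bilstm", "cnn"),
                              modalities = c("acc", "gyr", "combined"),
                              overlap_frac = 0.1,
                              drop_fraction = 2 / 3,
                              threshold = 0.5,
                              rf_search_budget = 6L,
                              bilstm = list(max_epochs = 10L, patience = 3L),
                              cnn = list(max_epochs = 4L, patience = 4L,
                                         lr = c(1e-3, 2e-3),
                                         batch_size = 16L, restarts = 2L),
                              seed = 1L,
                              keep_scores = TRUE,
                              out_dir = NULL) {
  models <- match.arg(models, c("rf", "bilstm", "cnn"), several.ok = TRUE)
  modalities <- match.arg(modalities, c("acc", "gyr", "combined"),
                          several.ok = TRUE)
  if (!inherits(sim, "fm_sim_config")) sim <- do.call(sim_config, sim)
  if (!inherits(filter, "fm_filter_spec")) filter <- do.call(filter_spec, filter)
  if (sim$trial_duration < 8)
    stop("trials must be at least 8 s long for the spectrogram representation")
  structure(list(
    n_trials = as.integer(n_trials), sim = sim, filter = filter,
    n_splits = as.integer(n_splits), n_test = as.integer(n_test),
    n_val = as.integer(n_val), models = models, modalities = modalities,
    overlap_frac = overlap_frac, drop_fraction = drop_fraction,
    threshold = threshold, rf_search_budget = as.integer(rf_search_budget),
    bilstm = bilstm, cnn = cnn, seed = as.integer(seed),
    keep_scores = isTRUE(keep_scores), out_dir = out_dir),
    class = "fm_experiment_config")
}

#' Run the full detection experiment
#'
#' Orchestrates the pipeline end to end: simulate a cohort, preprocess
#' every trial (bandpass + functional gyroscope alignment), derive window
#' labels from the perception presses, build the three data
#' representations, and -- for every Monte Carlo split, modality, and
#' model -- rebalance the training partition, train, score the held-out
#' test trials, and compute the detection metrics.  The same splits are
#' used for every representation so comparisons are paired.
#'
#' @param config An [experiment_config()].
#' @return An object of class `fm_experiment`: `results` (one row per
#'   split x model x modality with all metrics and confusion counts),
#'   `scores` (per-cell test labels/scores when `keep_scores`), `splits`,
#'   `config`, and `elapsed` timings per stage.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "fm_experiment_config"))
  t0 <- proc.time()[3]
  timing <- c()
  tick <- function(name) {
    t1 <- proc.time()[3]
    timing[name] <<- t1 - t0
    t0 <<- t1
  }

  cohort <- make_cohort(config$n_trials, config$sim, config$seed)
  tick("simulate")

  proc <- lapply(cohort, function(el)
    preprocess_trial(el$trial, el$calibration, config$filter))
  tick("preprocess")

  fs <- config$sim$fs
  n_samples <- dim(proc[[1]]$acc)[1]
  grid_short <- segment_windows(n_samples, 0.5, 0.5, fs)
  grid_long <- segment_windows(n_samples, 8, 1, fs)
  labels_short <- lapply(proc, function(tr)
    label_windows(grid_short, presses_to_events(tr$press_times),
                  config$overlap_frac))
  labels_long <- lapply(proc, function(tr)
    label_windows(grid_long, presses_to_events(tr$press_times),
                  config$overlap_frac))
  tick("label")

  reps <- build_representations(proc, grid_short, config)
  tick("represent")

  splits <- make_splits(seq_len(config$n_trials), config$n_splits,
                        config$n_test, config$n_val,
                        seed = derive_seed(config$seed, 90L))

  rows <- list()
  scores_store <- list()
  for (sp in splits) {
    for (mod in config$modalities) {
      for (model in config$models) {
        cell_seed <- derive_seed(config$seed,
                                 200L + sp$split_id * 13L +
                                   match(mod, c("acc", "gyr", "combined")) * 3L +
                                   match(model, c("rf", "bilstm", "cnn")))
        res <- run_cell(model, mod, sp, reps, proc, grid_short, grid_long,
                        labels_short, labels_long, config, cell_seed)
        met <- res$metrics
        rows[[length(rows) + 1L]] <- data.frame(
          split_id = sp$split_id, model = model, modality = mod,
          accuracy = met$accuracy, sensitivity = met$sensitivity,
          specificity = met$specificity, ppv = met$ppv, f1 = met$f1,
          auroc = met$auroc,
          tp = met$confusion["tp"], fp = met$confusion["fp"],
          fn = met$confusion["fn"], tn = met$confusion["tn"],
          row.names = NULL)
        if (config$keep_scores) {
          key <- sprintf("split%d_%s_%s", sp$split_id, model, mod)
          scores_store[[key]] <- list(labels = res$labels, scores = res$scores)
        }
      }
    }
  }
  tick("train_evaluate")

  out <- structure(list(
    results = do.call(rbind, rows),
    scores = scores_store,
    splits = splits,
    config = config,
    elapsed = timing), class = "fm_experiment")

  if (!is.null(config$out_dir)) write_experiment(out, config$out_dir)
  out
}

# Representations shared across splits: per-trial feature matrices and
# time-series tensors per single modality (combined views are assembled by
# concatenation), and trial-level spectrograms.
build_representations <- function(proc, grid_short, config) {
  needs <- unique(unlist(lapply(config$modalities, function(m)
    if (m == "combined") c("acc", "gyr") else m)))
  reps <- list()
  for (m in needs) {
    if ("rf" %in% config$models)
      reps$features[[m]] <- lapply(proc, function(tr)
        extract_feature_matrix(tr, grid_short, m))
    if ("bilstm" %in% config$models)
      reps$tensors[[m]] <- lapply(proc, function(tr)
        build_timeseries_tensors(tr, grid_short, m))
    if ("cnn" %in% config$models)
      reps$specs[[m]] <- lapply(proc, function(tr) trial_spectrogram(tr, m))
  }
  reps
}

bind_modality <- function(per_trial_list, modality, what = c("matrix", "tensor", "spec")) {
  what <- match.arg(what)
  if (modality != "combined") return(per_trial_list[[modality]])
  a <- per_trial_list$acc; g <- per_trial_list$gyr
  lapply(seq_along(a), function(i) {
    if (what == "matrix") return(cbind(a[[i]], g[[i]]))
    da <- dim(a[[i]]); dg <- dim(g[[i]])
    if (what == "tensor") {
      out <- array(0, dim = c(da[1], da[2], da[3] + dg[3]))
      out[, , seq_len(da[3])] <- a[[i]]
      out[, , da[3] + seq_len(dg[3])] <- g[[i]]
    } else {
      out <- array(0, dim = c(da[1], da[2], da[3] + dg[3]))
      out[, , seq_len(da[3])] <- a[[i]]
      out[, , da[3] + seq_len(dg[3])] <- g[[i]]
    }
    out
  })
}

run_cell <- function(model, mod, sp, reps, proc, grid_short, grid_long,
                     labels_short, labels_long, config, cell_seed) {
  if (model == "cnn") {
    grid <- grid_long; labels <- labels_long
  } else {
    grid <- grid_short; labels <- labels_short
  }
  y_train_full <- unlist(labels[sp$train], use.names = FALSE)
  keep <- rebalance_training(y_train_full, config$drop_fraction,
                             seed = derive_seed(cell_seed, 1L))
  y_train <- y_train_full[keep]
  y_val <- unlist(labels[sp$validation], use.names = FALSE)
  y_test <- unlist(labels[sp$test], use.names = FALSE)

  if (model == "rf") {
    feats <- bind_modality(reps$features, mod, "matrix")
    x_train <- do.call(rbind, feats[sp$train])[keep, , drop = FALSE]
    x_val <- do.call(rbind, feats[sp$validation])
    x_test <- do.call(rbind, feats[sp$test])
    fit <- train_rf(x_train, y_train, x_val, y_val,
                    search_budget = config$rf_search_budget,
                    seed = derive_seed(cell_seed, 2L))
    scores <- predict(fit, x_test)
  } else if (model == "bilstm") {
    tens <- bind_modality(reps$tensors, mod, "tensor")
    x_train <- abind_windows(tens[sp$train])[keep, , , drop = FALSE]
    std <- fit_standardizer(x_train)
    x_train <- apply_standardizer(x_train, std)
    x_val <- apply_standardizer(abind_windows(tens[sp$validation]), std)
    x_test <- apply_standardizer(abind_windows(tens[sp$test]), std)
    args <- c(list(x = x_train, y = y_train, val_x = x_val, val_y = y_val,
                   seed = derive_seed(cell_seed, 2L)), config$bilstm)
    fit <- do.call(train_bilstm, args)
    scores <- predict(fit, x_test)
  } else {
    specs <- bind_modality(reps$specs, mod, "spec")
    n_frames <- grid_long$n_window_samples[1] - 15L
    window_set <- function(trials, keep_idx = NULL) {
      trial_idx <- rep(trials, each = nrow(grid_long))
      frame0 <- rep(grid_long$start_sample, times = length(trials))
      if (!is.null(keep_idx)) {
        trial_idx <- trial_idx[keep_idx]; frame0 <- frame0[keep_idx]
      }
      list(trial = trial_idx, frame0 = frame0)
    }
    # per-bin standardization from training trials only; trials are
    # standardized once up front so window fetches are plain slices
    train_ws <- window_set(sp$train, keep)
    std <- fit_spec_standardizer(specs, sp$train)
    specs_z <- lapply(specs, function(s) {
      for (c in seq_len(dim(s)[3]))
        s[, , c] <- (s[, , c] - std$center[, c]) / std$scale[, c]
      s
    })
    mk <- function(ws) spec_window_set(specs_z, ws$trial, ws$frame0,
                                       n_frames = n_frames)
    # early stopping / restart selection monitors a thinned validation
    # grid (every other window; adjacent stride-1 windows overlap 7/8)
    val_thin <- seq(1L, nrow(grid_long), by = 2L)
    val_ws <- window_set(sp$validation)
    thin_idx <- as.vector(outer(val_thin, (seq_along(sp$validation) - 1L) *
                                  nrow(grid_long), "+"))
    val_ws <- list(trial = val_ws$trial[thin_idx],
                   frame0 = val_ws$frame0[thin_idx])
    y_val_thin <- unlist(lapply(labels[sp$validation],
                                function(l) l[val_thin]), use.names = FALSE)
    args <- c(list(x = mk(train_ws), y = y_train,
                   val_x = mk(val_ws), val_y = y_val_thin,
                   seed = derive_seed(cell_seed, 2L)), config$cnn)
    fit <- do.call(train_cnn, args)
    scores <- predict(fit, mk(window_set(sp$test)))
  }
  list(metrics = compute_metrics(y_test, scores, config$threshold),
       labels = y_test, scores = scores)
}

abind_windows <- function(tensor_list) {
  d1 <- dim(tensor_list[[1]])
  n <- sum(vapply(tensor_list, function(x) dim(x)[1], 0))
  out <- array(0, dim = c(n, d1[2], d1[3]))
  at <- 0L
  for (x in tensor_list) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

write_experiment <- function(exp, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # the hash stamps the scientific configuration; output paths excluded
  hash <- config_hash(unclass(exp$config)[setdiff(names(exp$config), "out_dir")])
  res <- exp$results
  res$config_hash <- hash
  data.table::fwrite(res, file.path(out_dir, "metrics.csv"))
  splits_plain <- lapply(exp$splits, function(sp)
    list(split_id = sp$split_id, test = sp$test,
         validation = sp$validation, train = sp$train))
  jsonlite::write_json(list(config_hash = hash, splits = splits_plain),
                       file.path(out_dir, "splits.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' @export
print.fm_experiment <- function(x, ...) {
  cat(sprintf("Fetal movement detection experiment: %d trials, %d split(s)\n",
              x$config$n_trials, x$config$n_splits))
  print(summary(x), digits = 3)
  invisible(x)
}

#' Summarize an experiment across splits
#'
#' @param object An `fm_experiment`.
#' @param ... Unused.
#' @return A data.frame with mean metrics per model x modality.
#' @export
summary.fm_experiment <- function(object, ...) {
  res <- object$results
  agg <- aggregate(res[, c("accuracy", "sensitivity", "specificity",
                           "ppv", "f1", "auroc")],
                   by = list(model = res$model, modality = res$modality),
                   FUN = mean)
  agg[order(agg$model, agg$modality), ]
}

#' Plot experiment AUROC by model and modality
#'
#' @param x An `fm_experiment`.
#' @param metric Metric column to plot (default `"auroc"`).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.fm_experiment <- function(x, metric = "auroc", ...) {
  agg <- summary(x)
  tab <- tapply(agg[[metric]], list(agg$modality, agg$model), mean)
  barplot(tab, beside = TRUE, legend.text = rownames(tab),
          ylab = toupper(metric), ylim = c(0, 1), ...)
  invisible(x)
}
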