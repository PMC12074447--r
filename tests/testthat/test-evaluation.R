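test_that("split plans have the advertised sizes and are disjoint", {
  plans <- make_splits(1:49, n_splits = 10, n_test = 6, n_val = 6, seed = 1)
  expect_length(plans, 10L)
  for (sp in plans) {
    expect_length(sp$test, 6L)
    expect_length(sp$validation, 6L)
    expect_length(sp$train, 37L)
    expect_length(intersect(sp$test, sp$validation), 0L)
    expect_length(intersect(sp$test, sp$train), 0L)
    expect_setequal(c(sp$test, sp$validation, sp$train), 1:49)
  }
  expect_identical(make_splits(1:49, seed = 4), make_splits(1:49, seed = 4))
  expect_length(make_splits(1:20, n_splits = 1, seed = 2), 1L)
  expect_error(make_splits(1:10, n_test = 6, n_val = 6), "too few")
})

test_that("every trial appears in test sets with roughly uniform frequency", {
  tally <- integer(20)
  for (s in 1:300) {
    sp <- make_splits(1:20, n_splits = 1, n_test = 4, n_val = 4, seed = s)[[1]]
    tally[sp$test] <- tally[sp$test] + 1L
  }
  expected <- 300 * 4 / 20
  expect_true(all(abs(tally - expected) < 5 * sqrt(expected)))
})

test_that("metrics reproduce hand-computed ratios exactly", {
  # confusion TP=80 FP=53 FN=20 TN=247
  labels <- c(rep(1, 100), rep(0, 300))
  scores <- c(rep(1, 80), rep(0, 20), rep(1, 53), rep(0, 247))
  m <- compute_metrics(labels, scores, threshold = 0.5)
  expect_equal(m$confusion, c(tp = 80, fp = 53, fn = 20, tn = 247))
  expect_equal(m$sensitivity, 80 / 100, tolerance = 1e-12)
  expect_equal(m$specificity, 247 / 300, tolerance = 1e-12)
  expect_equal(m$ppv, 80 / 133, tolerance = 1e-12)
  expect_equal(m$f1, 2 * (80 / 133) * 0.8 / (80 / 133 + 0.8), tolerance = 1e-12)
  expect_equal(m$accuracy, 327 / 400, tolerance = 1e-12)
  cm <- format_confusion(m)
  expect_match(cm["tp"], "^20.0% \\(80\\)$")
  expect_match(cm["tn"], "^61.8% \\(247\\)$")
})

test_that("metric edge cases follow the stated conventions", {
  expect_error(compute_metrics(numeric(0), numeric(0)), "empty")
  m <- compute_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  for (k in c("accuracy", "sensitivity", "specificity", "ppv", "f1", "auroc"))
    expect_equal(m[[k]], 1)
  # constant scores: chance AUROC by midrank convention
  expect_equal(compute_metrics(c(1, 0, 1, 0), rep(0.4, 4))$auroc, 0.5)
  # no predicted positives: PPV undefined, reported as 0 and flagged
  m0 <- compute_metrics(c(1, 0, 1, 0), c(0.1, 0.1, 0.2, 0.3), threshold = 0.9)
  expect_equal(m0$ppv, 0)
  expect_true("ppv" %in% m0$undefined)
  # single-class labels: AUROC undefined, flagged
  m1 <- compute_metrics(c(0, 0, 0), c(0.2, 0.5, 0.7))
  expect_true("auroc" %in% m1$undefined)
})

test_that("rank AUROC equals the trapezoidal ROC area", {
  set.seed(6)
  for (i in 1:50) {
    n <- sample(20:100, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), sample(c(1, 2, 7), 1))  # induce ties sometimes
    expect_equal(fmdetect:::auroc_rank(labels, scores),
                 oracle_auroc_trapezoid(labels, scores), tolerance = 1e-9)
  }
})

test_that("rank AUROC agrees with an external reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  labels <- rbinom(80, 1, 0.5)
  scores <- runif(80)
  ref <- as.numeric(suppressMessages(pROC::auc(labels, scores,
                                               direction = "<", quiet = TRUE)))
  expect_equal(fmdetect:::auroc_rank(labels, scores), ref, tolerance = 1e-12)
})

test_that("paired tests behave at the boundaries and in between", {
  a <- c(0.7, 0.8, 0.75, 0.9, 0.85)
  expect_equal(paired_test(a, a), 1)
  expect_equal(paired_test(a, a + 0.1), 0)   # constant non-zero differences
  set.seed(2)
  b <- a + rnorm(5, 0, 0.01)
  expect_equal(paired_test(a, b), paired_test(b, a))
  big_a <- runif(10, 0.8, 0.9)
  big_b <- big_a - 0.5 + rnorm(10, 0, 0.01)
  expect_lt(paired_test(big_a, big_b), 0.001)
  expect_lt(paired_test(big_a, big_b, method = "wilcoxon"), 0.01)
  expect_error(paired_test(1:3, 1:4), "paired")
})

test_that("threshold sweeps cover the 0.1-0.9 grid with monotone trends", {
  set.seed(13)
  labels <- rbinom(200, 1, 0.3)
  scores <- runif(200)
  sw <- threshold_sweep(labels, scores)
  expect_equal(nrow(sw), 9L)
  expect_equal(sw$threshold, seq(0.1, 0.9, by = 0.1))
  for (i in 1:100) {
    l <- rbinom(60, 1, 0.5); s <- runif(60)
    if (length(unique(l)) < 2) next
    tab <- threshold_sweep(l, s)
    expect_true(all(diff(tab$sensitivity) <= 1e-12))
    expect_true(all(diff(tab$specificity) >= -1e-12))
  }
  perfect <- threshold_sweep(labels, labels)
  expect_true(all(perfect$accuracy == 1))
  expect_equal(nrow(unique(perfect[, -1])), 1L)
})

test_that("training-size sweeps nest subsets and keep fraction one exact", {
  seen <- list()
  pipeline <- function(train_ids) {
    seen[[length(seen) + 1L]] <<- sort(train_ids)
    list(auroc = length(train_ids) / 20)
  }
  out <- training_size_sweep(pipeline, 1:20, seed = 3)
  expect_equal(out$fraction, c(0.25, 0.5, 0.75, 1))
  expect_equal(out$n_train_trials, c(5L, 10L, 15L, 20L))
  expect_true(all(seen[[1]] %in% seen[[2]]))
  expect_true(all(seen[[2]] %in% seen[[3]]))
  expect_identical(seen[[4]], 1:20)       # fraction 1 is the untouched full set
  expect_equal(out$auroc, c(0.25, 0.5, 0.75, 1))
  expect_error(training_size_sweep(pipeline, 1:20, fractions = c(0, 0.5)),
               "fractions")
  # 4 fractions x 3 models = 12 rows when swept per model
  rows <- do.call(rbind, lapply(1:3, function(m)
    cbind(model = m, training_size_sweep(pipeline, 1:20, seed = m))))
  expect_equal(nrow(rows), 12L)
})
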