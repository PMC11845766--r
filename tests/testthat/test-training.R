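# Protocol and metrics: stratified splits, fivefold partitions, the five
# metric formulas against an independent oracle, AUC null behaviour, and a
# separability sanity run of the training loop.

test_that("stratified 70:10:20 splits are exact on balanced classes", {
  labels <- rep(0:1, each = 50)
  sp <- stratified_split(labels, seed = 1)
  expect_equal(length(sp$train), 70L)
  expect_equal(length(sp$val), 10L)
  expect_equal(length(sp$test), 20L)
  # disjoint and exhaustive
  all_idx <- c(sp$train, sp$val, sp$test)
  expect_equal(sort(all_idx), 1:100)
  # per-class proportions within one sample
  for (part in sp) {
    expect_lte(abs(sum(labels[part] == 0) - sum(labels[part] == 1)), 1L)
  }
  # determinism
  expect_identical(sp, stratified_split(labels, seed = 1))
  expect_false(identical(sp, stratified_split(labels, seed = 2)))
})

test_that("degenerate ratios and undersized classes are handled", {
  labels <- rep(0:1, each = 10)
  all_train <- stratified_split(labels, ratios = c(1, 0, 0), seed = 3)
  expect_equal(sort(all_train$train), 1:20)
  expect_equal(length(all_train$test), 0L)
  expect_error(stratified_split(c(0, 0, 0, 1, 1), seed = 1),
               "class 1 has fewer than 3")
})

test_that("imbalanced splits stay within one sample of the ratios", {
  labels <- withr::with_seed(4, sample(0:5, 243, replace = TRUE,
                                       prob = c(.3, .25, .2, .1, .1, .05)))
  sp <- stratified_split(labels, seed = 5)
  for (cl in 0:5) {
    n_cl <- sum(labels == cl)
    expect_lte(abs(sum(labels[sp$train] == cl) - 0.7 * n_cl), 1)
    expect_lte(abs(sum(labels[sp$test] == cl) - 0.2 * n_cl), 1)
  }
})

test_that("fivefold partitions are stratified and exhaustive", {
  labels <- rep(0:1, each = 25)
  folds <- make_folds(labels, k = 5, seed = 6)
  expect_equal(length(folds), 5L)
  test_union <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(test_union, 1:50)            # each sample in one test fold
  for (f in folds) {
    expect_equal(length(f$test), 10L)
    expect_equal(sort(c(f$train, f$test)), 1:50)
    expect_lte(abs(sum(labels[f$test] == 0) - 5), 1)
  }
  expect_error(make_folds(c(0, 0, 0, 1), k = 5), "fewer than k")
})

test_that("confusion matrices count true-by-predicted pairs", {
  cm <- confusion_matrix(c(0, 0, 1), c(0, 1, 1), n_classes = 2)
  expect_equal(unname(cm), matrix(c(1L, 0L, 1L, 1L), 2))
  y <- withr::with_seed(7, sample(0:5, 60, replace = TRUE))
  cm6 <- confusion_matrix(y, y)
  expect_true(all(cm6[upper.tri(cm6)] == 0) && all(cm6[lower.tri(cm6)] == 0))
  expect_equal(sum(cm6), 60L)
  expect_equal(unname(diag(cm6)), as.vector(unname(table(factor(y, 0:5)))))
  expect_error(confusion_matrix(0, 6, n_classes = 6), "out of range")
})

test_that("the five metric formulas match hand computation", {
  m <- binary_metrics_from_counts(TP = 8, TN = 9, FP = 2, FN = 1)
  expect_equal(m$precision, 0.800, tolerance = 1e-4)
  expect_equal(m$sensitivity, 0.8889, tolerance = 1e-4)
  expect_equal(m$specificity, 0.8182, tolerance = 1e-4)
  expect_equal(m$accuracy, 0.85, tolerance = 1e-12)
  expect_equal(m$f1, 0.8421, tolerance = 1e-4)

  perfect <- binary_metrics_from_counts(5, 5, 0, 0)
  expect_true(all(unlist(perfect) == 1))
  zero_tp <- suppressWarnings(binary_metrics_from_counts(0, 5, 0, 3))
  expect_equal(zero_tp$sensitivity, 0)
  expect_equal(zero_tp$f1, 0)
  w <- testthat::capture_warnings(binary_metrics_from_counts(0, 5, 0, 0))
  expect_true(any(grepl("undefined", w)))
})

test_that("metrics agree with an independent oracle on 1,000 quadruples", {
  # independent oracle: direct rational evaluation of the printed formulas
  oracle <- function(TP, TN, FP, FN) {
    div <- function(a, b) if (b == 0) 0 else a / b
    prec <- div(TP, TP + FP)
    sens <- div(TP, TP + FN)
    c(accuracy = div(TP + TN, TP + TN + FN + FP),
      specificity = div(TN, TN + FP),
      sensitivity = sens, precision = prec,
      f1 = if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens))
  }
  quads <- withr::with_seed(8, matrix(rpois(4000, 5), ncol = 4))
  for (i in seq_len(nrow(quads))) {
    got <- suppressWarnings(
      binary_metrics_from_counts(quads[i, 1], quads[i, 2],
                                 quads[i, 3], quads[i, 4]))
    expect_equal(unlist(got), oracle(quads[i, 1], quads[i, 2],
                                     quads[i, 3], quads[i, 4]),
                 tolerance = 1e-12)
  }
})

test_that("multiclass reduction is one-vs-rest with macro averaging", {
  cm <- diag(c(5L, 8L, 3L, 4L, 6L, 2L))
  rep_all <- multiclass_metrics(cm)
  expect_equal(rep_all$accuracy, 1)
  expect_true(all(rep_all$per_class$f1 == 1))
  expect_equal(rep_all$macro$f1, 1)

  # macro F1 is exactly the mean of per-class F1
  y_true <- withr::with_seed(9, sample(0:5, 300, replace = TRUE))
  y_pred <- withr::with_seed(10, sample(0:5, 300, replace = TRUE))
  r <- multiclass_metrics(confusion_matrix(y_true, y_pred))
  expect_equal(r$macro$f1, mean(r$per_class$f1))
  expect_equal(r$accuracy, sum(diag(r$confusion)) / 300)
  expect_error(multiclass_metrics(matrix(0, 2, 3)), "square")
})

test_that("chance-level predictions give chance-level accuracy", {
  n <- 6000
  y_true <- withr::with_seed(11, sample(0:5, n, replace = TRUE))
  y_pred <- withr::with_seed(12, sample(0:5, n, replace = TRUE))
  r <- multiclass_metrics(confusion_matrix(y_true, y_pred))
  expect_lt(abs(r$accuracy - 1 / 6), 0.05)
})

test_that("rank AUC is 0.5 under the null and matches pROC", {
  n <- 2000
  scores <- withr::with_seed(13, runif(n))
  truth <- withr::with_seed(14, rbinom(n, 1, 0.3))
  auc <- trispectrakan:::rank_auc(scores, truth)
  expect_lt(abs(auc - 0.5), 0.05)
  # independent implementation as cross-check
  expect_equal(auc, as.numeric(pROC::auc(pROC::roc(truth, scores,
                                                   quiet = TRUE,
                                                   direction = "<"))),
               tolerance = 1e-12)
  # perfect separation
  expect_equal(trispectrakan:::rank_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
})

test_that("training separates linearly separable synthetic features", {
  # two classes whose mfcc blocks carry opposite constant offsets
  n <- 60
  triples <- withr::with_seed(15, {
    lapply(seq_len(n), function(i) {
      lab <- (i - 1L) %% 2L
      off <- if (lab == 0L) -1 else 1
      structure(list(mfcc = matrix(rnorm(20 * 259, mean = off), 20),
                     chroma = matrix(rnorm(12 * 259), 12),
                     mspec = matrix(rnorm(128 * 259), 128),
                     n_frames = 259L, label = lab),
                class = "feature_triple")
    })
  })
  labels <- vapply(triples, `[[`, 0L, "label")
  cfg <- model_config("trispectrakan", n_classes = 6L)
  model <- build_trispectrakan(cfg, seed = 21)
  model <- train_model(model, triples[1:48], labels[1:48],
                       triples[49:60], labels[49:60],
                       train_config(epochs = 4, batch_size = 16,
                                    seed = 22))
  h <- tidy(model)
  expect_lte(nrow(h), 4L)                       # early-stop bound
  expect_gte(h$train_acc[nrow(h)], 0.99)
  # evaluation report is internally consistent
  r <- evaluate_model(model, triples[49:60], labels[49:60])
  expect_equal(r$metrics$accuracy,
               sum(diag(r$metrics$confusion)) / sum(r$metrics$confusion))
  expect_equal(glance(r$metrics)$accuracy, r$metrics$accuracy)
})

test_that("fold reports carry per-fold values and their mean", {
  mk_report <- function(acc) {
    cm <- matrix(0L, 6, 6)
    diag(cm) <- round(acc * 10)
    cm[1, 2] <- 10L - round(acc * 10)
    structure(list(metrics = multiclass_metrics(cm)),
              class = "evaluation_report")
  }
  fr <- fold_report(list(mk_report(0.9), mk_report(0.8)))
  acc_row <- fr[fr$metric == "accuracy", ]
  expect_equal(acc_row$mean, mean(c(acc_row$fold_1, acc_row$fold_2)))
})

test_that("training is bit-reproducible under a fixed seed", {
  triples <- random_triples(24, seed = 23)
  labels <- vapply(triples, `[[`, 0L, "label")
  run_once <- function() {
    model <- build_trispectrakan(seed = 24)
    model <- train_model(model, triples[1:18], labels[1:18],
                         triples[19:24], labels[19:24],
                         train_config(epochs = 2, batch_size = 16,
                                      seed = 25))
    tidy(model)
  }
  h1 <- run_once()
  h2 <- run_once()
  expect_identical(h1, h2)
  expect_equal(h1$lr[1], 0.001)   # Nadam at the configured initial rate
})
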