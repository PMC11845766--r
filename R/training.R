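# Training and evaluation protocol: stratified 70:10:20 splits inside a
# stratified fivefold scheme, Nadam optimization of sparse categorical
# cross-entropy, plateau learning-rate decay, early stopping, and the five
# headline metrics computed one-vs-rest from the confusion matrix.

#' Training configuration
#'
#' Defaults are the selected values: batch 32, initial learning rate 0.001,
#' 50 epochs, Nadam. The plateau schedule halves the learning rate after 5
#' stagnant validation epochs (floor 1e-5) and early stopping fires after
#' 10.
#'
#' @param batch_size Mini-batch size.
#' @param learning_rate Initial learning rate.
#' @param epochs Maximum number of epochs.
#' @param optimizer Only `"nadam"` is implemented.
#' @param plateau_patience Epochs without val-loss improvement before the
#'   learning rate is multiplied by `plateau_factor`.
#' @param plateau_factor Learning-rate decay multiplier.
#' @param min_lr Learning-rate floor.
#' @param early_stop_patience Stagnant epochs before training stops.
#' @param seed Integer seed for shuffling and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, learning_rate = 0.001,
                         epochs = 50L, optimizer = "nadam",
                         plateau_patience = 5L, plateau_factor = 0.5,
                         min_lr = 1e-5, early_stop_patience = 10L,
                         seed = 0L) {
  stopifnot(optimizer == "nadam", batch_size >= 1L, learning_rate > 0,
            epochs >= 1L)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 optimizer = optimizer,
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor, min_lr = min_lr,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Stratified train/validation/test split
#'
#' Splits indices so that each class is represented in each part in the
#' requested proportions (within one sample, by largest remainder).
#'
#' @param labels Integer or factor class labels.
#' @param ratios Length-3 proportions (train, val, test) summing to 1.
#' @param seed Integer seed.
#' @return List with integer index vectors `train`, `val`, `test`
#'   (disjoint, exhaustive).
#' @export
stratified_split <- function(labels, ratios = c(0.70, 0.10, 0.20),
                             seed = 0L) {
  stopifnot(length(ratios) == 3L, all(ratios >= 0),
            abs(sum(ratios) - 1) < 1e-9)
  labels <- as.vector(labels)
  parts <- list(train = integer(0), val = integer(0), test = integer(0))
  n_nonzero <- sum(ratios > 0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < 3L && n_nonzero > 1L) {
      abort(paste0("class ", cl, " has fewer than 3 samples"))
    }
    idx <- with_seed(derive_seed(seed, match(cl, sort(unique(labels)))),
                     sample(idx))
    target <- ratios * length(idx)
    base <- floor(target)
    rem <- target - base
    extra <- length(idx) - sum(base)
    if (extra > 0) {
      give <- order(rem, decreasing = TRUE)[seq_len(extra)]
      base[give] <- base[give] + 1L
    }
    ends <- cumsum(base)
    starts <- c(1L, head(ends, -1L) + 1L)
    for (j in 1:3) {
      if (base[j] > 0) {
        parts[[j]] <- c(parts[[j]], idx[starts[j]:ends[j]])
      }
    }
  }
  lapply(parts, sort)
}

#' Stratified k-fold partitions
#'
#' @param labels Integer or factor class labels.
#' @param k Number of folds (every class must have at least `k` members).
#' @param seed Integer seed.
#' @return List of `k` lists, each with `train` and `test` index vectors;
#'   every sample appears in exactly one test fold.
#' @export
make_folds <- function(labels, k = 5L, seed = 0L) {
  stopifnot(k >= 2L)
  labels <- as.vector(labels)
  fold_of <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      abort(paste0("class ", cl, " has fewer than k = ", k, " samples"))
    }
    idx <- with_seed(derive_seed(seed, 7, match(cl, sort(unique(labels)))),
                     sample(idx))
    fold_of[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

# eval-mode forward in mini-batches; returns logits matrix
model_logits <- function(model, inputs, batch_size = 32L) {
  B <- dim(inputs$mfcc)[4]
  out <- NULL
  for (s in seq(1L, B, by = batch_size)) {
    ix <- s:min(B, s + batch_size - 1L)
    batch <- lapply(inputs, function(a) a[, , , ix, drop = FALSE])
    out <- rbind(out, model_forward(model, batch, training = FALSE))
  }
  out
}

ce_loss_acc <- function(logits, labels) {
  probs <- softmax_rows(logits)
  p_true <- probs[cbind(seq_along(labels), labels + 1L)]
  list(loss = mean(-log(pmax(p_true, 1e-12))),
       acc = mean(max.col(probs, ties.method = "first") - 1L == labels))
}

#' Train a classifier
#'
#' Mini-batch Nadam on sparse categorical cross-entropy with plateau
#' learning-rate decay and early stopping on validation loss. All
#' randomness (shuffling, dropout) is driven by `cfg$seed`, so a rerun on
#' the same data reproduces the same trajectory on a single CPU thread.
#'
#' @param model A `lung_sound_model` (modified in place and returned).
#' @param train_triples,val_triples Lists of `feature_triple`s, or
#'   pre-stacked input lists from `stack_triples()`.
#' @param train_labels,val_labels Integer class codes (0-based).
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return The model, with a `history` attribute: a tibble of per-epoch
#'   learning rate, train/val loss and accuracy.
#' @export
train_model <- function(model, train_triples, train_labels,
                        val_triples, val_labels,
                        cfg = train_config(), verbose = FALSE) {
  tr_in <- if (is.list(train_triples) && !is.null(train_triples$mfcc))
    train_triples else stack_triples(train_triples)
  va_in <- if (is.list(val_triples) && !is.null(val_triples$mfcc))
    val_triples else stack_triples(val_triples)
  n_tr <- dim(tr_in$mfcc)[4]
  if (n_tr < 1L || dim(va_in$mfcc)[4] < 1L) {
    abort("train and validation sets must be non-empty")
  }
  stopifnot(length(train_labels) == n_tr)

  lr <- cfg$learning_rate
  best_val <- Inf
  stagnant <- 0L
  history <- list()
  step <- 0L
  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n_tr)
    ep_loss <- 0
    ep_correct <- 0L
    for (s in seq(1L, n_tr, by = cfg$batch_size)) {
      ix <- ord[s:min(n_tr, s + cfg$batch_size - 1L)]
      batch <- lapply(tr_in, function(a) a[, , , ix, drop = FALSE])
      y <- train_labels[ix]
      logits <- model_forward(model, batch, training = TRUE)
      probs <- softmax_rows(logits)
      p_true <- probs[cbind(seq_along(y), y + 1L)]
      loss <- mean(-log(pmax(p_true, 1e-12)))
      if (!is.finite(loss)) {
        abort(paste0("non-finite loss at epoch ", epoch,
                     " (exploding gradients or bad input)"))
      }
      ep_loss <- ep_loss + loss * length(ix)
      ep_correct <- ep_correct +
        sum(max.col(probs, ties.method = "first") - 1L == y)
      d_logits <- probs
      d_logits[cbind(seq_along(y), y + 1L)] <-
        d_logits[cbind(seq_along(y), y + 1L)] - 1
      d_logits <- d_logits / length(y)
      model_backward(model, d_logits)
      step <- step + 1L
      nadam_step(model_layers(model), step, lr)
    }
    clear_caches(model_layers(model))
    val <- ce_loss_acc(model_logits(model, va_in, cfg$batch_size),
                       val_labels)
    history[[epoch]] <- tibble(
      epoch = epoch, lr = lr,
      train_loss = ep_loss / n_tr, train_acc = ep_correct / n_tr,
      val_loss = val$loss, val_acc = val$acc)
    if (verbose) {
      inform(sprintf(
        "epoch %3d lr %.2e train loss %.4f acc %.3f val loss %.4f acc %.3f",
        epoch, lr, ep_loss / n_tr, ep_correct / n_tr, val$loss, val$acc))
    }
    if (val$loss < best_val - 1e-6) {
      best_val <- val$loss
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
      if (stagnant >= cfg$early_stop_patience) break
      if (stagnant %% cfg$plateau_patience == 0L) {
        lr <- max(cfg$min_lr, lr * cfg$plateau_factor)
      }
    }
  }
  attr(model, "history") <- dplyr::bind_rows(history)
  model
}

#' Confusion matrix
#'
#' Entry `(i, j)` counts samples of true class `i` predicted as class `j`
#' (0-based codes map to rows/columns 1..n).
#'
#' @param y_true,y_pred Integer class codes in `[0, n_classes)`.
#' @param n_classes Number of classes.
#' @return `n_classes` x `n_classes` integer matrix with class labels as
#'   dimnames when `n_classes` is 6.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = 6L) {
  stopifnot(length(y_true) == length(y_pred))
  if (any(y_true < 0 | y_true >= n_classes) ||
      any(y_pred < 0 | y_pred >= n_classes)) {
    abort("labels out of range [0, n_classes)")
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L,
                                             y_pred[i] + 1L] + 1L
  }
  if (n_classes == 6L) dimnames(cm) <- list(DIAGNOSIS_LEVELS,
                                            DIAGNOSIS_LEVELS)
  cm
}

#' The five binary classification metrics from TP/TN/FP/FN counts
#'
#' Exact evaluation of
#' `accuracy = (TP + TN) / (TP + TN + FN + FP)`,
#' `specificity = TN / (TN + FP)`, `sensitivity = TP / (TP + FN)`,
#' `precision = TP / (TP + FP)` and
#' `F1 = 2 * precision * sensitivity / (precision + sensitivity)`.
#' A zero denominator yields 0 with a warning.
#'
#' @param TP,TN,FP,FN Non-negative counts.
#' @return Named list with `accuracy`, `specificity`, `sensitivity`,
#'   `precision`, `f1`.
#' @export
binary_metrics_from_counts <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn(paste0(what, " undefined (zero denominator); reported as 0"))
      return(0)
    }
    num / den
  }
  accuracy <- safe_div(TP + TN, TP + TN + FN + FP, "accuracy")
  specificity <- safe_div(TN, TN + FP, "specificity")
  sensitivity <- safe_div(TP, TP + FN, "sensitivity")
  precision <- safe_div(TP, TP + FP, "precision")
  f1 <- if (precision + sensitivity == 0) 0 else
    2 * precision * sensitivity / (precision + sensitivity)
  list(accuracy = accuracy, specificity = specificity,
       sensitivity = sensitivity, precision = precision, f1 = f1)
}

#' One-vs-rest multiclass metrics from a confusion matrix
#'
#' Reduces each class to a binary problem (TP on the diagonal, FP its
#' column, FN its row, TN the rest), evaluates the five metrics per class,
#' and averages them unweighted (macro). Overall accuracy is
#' `trace / total`.
#'
#' @param confusion Square count matrix from [confusion_matrix()].
#' @return A list of class `metrics_report` with `confusion`, `per_class`
#'   (tibble), `macro` (named list) and `accuracy`.
#' @export
multiclass_metrics <- function(confusion) {
  if (!is.matrix(confusion) || nrow(confusion) != ncol(confusion)) {
    abort("confusion matrix must be square")
  }
  n <- nrow(confusion)
  total <- sum(confusion)
  per <- list()
  for (c in seq_len(n)) {
    TP <- confusion[c, c]
    FP <- sum(confusion[, c]) - TP
    FN <- sum(confusion[c, ]) - TP
    TN <- total - TP - FP - FN
    m <- suppressWarnings(binary_metrics_from_counts(TP, TN, FP, FN))
    per[[c]] <- tibble(
      class = if (!is.null(rownames(confusion))) rownames(confusion)[c]
      else as.character(c - 1L),
      TP = TP, TN = TN, FP = FP, FN = FN,
      accuracy = m$accuracy, specificity = m$specificity,
      sensitivity = m$sensitivity, precision = m$precision, f1 = m$f1)
  }
  per_class <- dplyr::bind_rows(per)
  macro <- as.list(colMeans(per_class[, c("accuracy", "specificity",
                                          "sensitivity", "precision",
                                          "f1")]))
  structure(list(confusion = confusion, per_class = per_class,
                 macro = macro,
                 accuracy = sum(diag(confusion)) / total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: accuracy %.4f, macro F1 %.4f (%d samples)\n",
              x$accuracy, x$macro$f1, sum(x$confusion)))
  print(x$per_class)
  invisible(x)
}

#' Tidy a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return The per-class metric tibble (one row per class).
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' One-row summary of a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return One-row tibble with overall accuracy and macro-averaged
#'   specificity, sensitivity, precision and F1.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble(accuracy = x$accuracy,
         macro_specificity = x$macro$specificity,
         macro_sensitivity = x$macro$sensitivity,
         macro_precision = x$macro$precision,
         macro_f1 = x$macro$f1,
         n = sum(x$confusion))
}

# rank-based (Mann-Whitney) AUC of scores for a binary 0/1 outcome
rank_auc <- function(scores, truth) {
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a model on a test set
#'
#' Deterministic eval-mode prediction followed by the full metric report
#' and per-class one-vs-rest ROC/AUC.
#'
#' @param model A trained `lung_sound_model`.
#' @param test_triples List of `feature_triple`s or stacked inputs.
#' @param test_labels Integer class codes.
#' @param batch_size Prediction batch size.
#' @return A list of class `evaluation_report`: `metrics`
#'   (`metrics_report`), `auc` (named per-class vector), `roc` (tibble of
#'   ROC points per class), `predictions` (tibble).
#' @export
evaluate_model <- function(model, test_triples, test_labels,
                           batch_size = 32L) {
  te_in <- if (is.list(test_triples) && !is.null(test_triples$mfcc))
    test_triples else stack_triples(test_triples)
  if (dim(te_in$mfcc)[4] < 1L) abort("empty test set")
  logits <- model_logits(model, te_in, batch_size)
  probs <- softmax_rows(logits)
  y_pred <- max.col(probs, ties.method = "first") - 1L
  cm <- confusion_matrix(test_labels, y_pred,
                         n_classes = model$config$n_classes)
  metrics <- multiclass_metrics(cm)
  auc <- numeric(model$config$n_classes)
  roc_pts <- list()
  for (c in seq_len(model$config$n_classes)) {
    truth <- as.integer(test_labels == c - 1L)
    auc[c] <- rank_auc(probs[, c], truth)
    roc_pts[[c]] <- roc_points(probs[, c], truth,
                               model$class_labels[c])
  }
  names(auc) <- model$class_labels[seq_len(model$config$n_classes)]
  colnames(probs) <- paste0("p_", model$class_labels)
  structure(list(metrics = metrics, auc = auc,
                 roc = dplyr::bind_rows(roc_pts),
                 predictions = dplyr::bind_cols(
                   tibble(y_true = as.integer(test_labels),
                          y_pred = y_pred), as_tibble(probs))),
            class = "evaluation_report")
}

# full ROC curve by threshold sweep over the observed scores
roc_points <- function(scores, truth, class_name) {
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(truth[ord] == 1)
  fp <- cumsum(truth[ord] == 0)
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  tibble(class = class_name,
         threshold = c(Inf, scores[ord]),
         tpr = c(0, if (n1 > 0) tp / n1 else rep(0, length(tp))),
         fpr = c(0, if (n0 > 0) fp / n0 else rep(0, length(fp))))
}

#' @export
print.evaluation_report <- function(x, ...) {
  print(x$metrics)
  cat("per-class AUC:\n")
  print(round(x$auc, 4))
  invisible(x)
}

#' Table of per-fold metrics with their mean
#'
#' Assembles the cross-validation report: one column per fold, one row per
#' metric, plus the across-fold mean of each per-fold value (the mean of
#' per-fold accuracies, never a pooled-confusion accuracy).
#'
#' @param fold_reports List of `evaluation_report`s, one per fold.
#' @return Tibble with columns `metric`, `fold_1` ... `fold_k`, `mean`.
#' @export
fold_report <- function(fold_reports) {
  metrics <- c("accuracy", "specificity", "sensitivity", "precision", "f1")
  rows <- lapply(metrics, function(m) {
    vals <- vapply(fold_reports, function(r) {
      if (m == "accuracy") r$metrics$accuracy else r$metrics$macro[[m]]
    }, numeric(1))
    out <- as.list(c(vals, mean(vals)))
    names(out) <- c(paste0("fold_", seq_along(vals)), "mean")
    dplyr::bind_cols(tibble(metric = m), as_tibble(out))
  })
  dplyr::bind_rows(rows)
}

#' Plot a training history
#'
#' Loss and accuracy per epoch for the train and validation sets.
#'
#' @param object A trained model (with `history` attribute) or the history
#'   tibble itself.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lung_sound_model <- function(object, ...) {
  h <- attr(object, "history")
  if (is.null(h)) abort("model has no training history")
  df <- tidyr::pivot_longer(h, c("train_loss", "val_loss", "train_acc",
                                 "val_acc"),
                            names_to = c("set", "measure"),
                            names_sep = "_")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(y = NULL)
}

#' Per-epoch training history of a fitted model
#'
#' @param x A trained `lung_sound_model`.
#' @param ... Unused.
#' @return Tibble with epoch, learning rate, train/val loss and accuracy.
#' @export
tidy.lung_sound_model <- function(x, ...) {
  h <- attr(x, "history")
  if (is.null(h)) abort("model has no training history")
  h
}

#' One-row summary of a fitted model
#'
#' @param x A `lung_sound_model`.
#' @param ... Unused.
#' @return One-row tibble with variant, parameter count and (when trained)
#'   the final epoch's losses and accuracies.
#' @export
glance.lung_sound_model <- function(x, ...) {
  h <- attr(x, "history")
  out <- tibble(variant = x$variant, n_params = model_param_count(x))
  if (!is.null(h)) {
    out <- dplyr::bind_cols(out, h[nrow(h), c("epoch", "train_loss",
                                              "train_acc", "val_loss",
                                              "val_acc")])
  }
  out
}
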