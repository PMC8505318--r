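#' Train a probabilistic binary classifier
#'
#' `rsvm` is a radial-kernel support vector machine with Platt-style
#' probability calibration fit on the training data (features are
#' standardized on training statistics inside the fit);
#' `random_forest` is a probability forest. Both are seed-controlled.
#' The positive class is the second level of `y`.
#'
#' @param x samples x features matrix or data.frame.
#' @param y binary factor.
#' @param model_kind `"rsvm"` or `"random_forest"`.
#' @param hyperparams list; `cost`/`gamma` for the SVM, `num_trees`/
#'   `mtry` for the forest.
#' @param seed integer seed.
#' @return a `ppcs_model`; use [predict_prob()] for positive-class
#'   probabilities.
#' @export
train_classifier <- function(x, y, model_kind = c("rsvm", "random_forest"),
                             hyperparams = list(), seed = 1L) {
  model_kind <- match.arg(model_kind)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop_bad_arg("y has a single class")
  fit <- withr::with_seed(seed, switch(model_kind,
    rsvm = e1071::svm(x, y, kernel = "radial", probability = TRUE,
                      cost = hyperparams$cost %||% 1,
                      gamma = hyperparams$gamma %||% (1 / ncol(x)),
                      scale = apply(x, 2, sd) > 0),
    random_forest = ranger::ranger(
      x = x, y = y, probability = TRUE,
      num.trees = hyperparams$num_trees %||% 500L,
      mtry = hyperparams$mtry,
      num.threads = 1, seed = seed)))
  structure(list(fit = fit, kind = model_kind,
                 features = colnames(x), levels = levels(y),
                 positive = levels(y)[2], seed = seed),
            class = "ppcs_model")
}

#' Positive-class probabilities from a trained model
#'
#' @param model a [train_classifier()] result.
#' @param newdata samples x features matrix with the training features.
#' @return numeric vector of positive-class probabilities.
#' @export
predict_prob <- function(model, newdata) {
  stopifnot(inherits(model, "ppcs_model"))
  newdata <- as.matrix(newdata)[, model$features, drop = FALSE]
  if (model$kind == "rsvm") {
    pr <- predict(model$fit, newdata, probability = TRUE)
    unname(attr(pr, "probabilities")[, model$positive])
  } else {
    unname(predict(model$fit, data = newdata)$predictions[, model$positive])
  }
}

#' Repeated stratified k-fold cross-validated ROC performance
#'
#' Out-of-fold positive-class probabilities are collected for each
#' repetition and averaged across repetitions per sample; the reported
#' AUC and its DeLong CI are both computed on those averaged
#' probabilities (so `ci_low <= auc <= ci_high` holds by construction),
#' and per-repetition AUCs are returned alongside.
#'
#' @param x samples x features matrix.
#' @param y binary factor (positive = second level).
#' @param model_kind,hyperparams passed to [train_classifier()].
#' @param k folds (reduced with a warning when the minority class is
#'   smaller than `k`).
#' @param reps repetitions (default 10).
#' @param seed integer seed.
#' @return a `roc_result` list: `auc`, `ci_low`, `ci_high`, `se`,
#'   `auc_reps`, `probs` (rep-averaged out-of-fold), `labels`, `n_pos`,
#'   `n_neg`, `k`, `reps`.
#' @export
repeated_cv <- function(x, y, model_kind = "rsvm", k = 10L, reps = 10L,
                        seed = 1L, hyperparams = list()) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  minc <- min(table(y))
  if (minc < k) {
    warning("minority class smaller than k; using k = ", minc,
            call. = FALSE)
    k <- minc
  }
  prob_mat <- matrix(NA_real_, nrow(x), reps)
  auc_reps <- numeric(reps)
  for (r in seq_len(reps)) {
    folds <- make_folds(y, k, seed + 1000L * r)
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- train_classifier(x[tr, , drop = FALSE], y[tr], model_kind,
                              hyperparams, seed = seed + 1000L * r + f)
      prob_mat[!tr, r] <- predict_prob(fit, x[!tr, , drop = FALSE])
    }
    auc_reps[r] <- auc_mann_whitney(prob_mat[, r], y)
  }
  probs <- rowMeans(prob_mat)
  ci <- delong_ci(probs, y)
  structure(list(auc = ci$auc, ci_low = ci$ci_low, ci_high = ci$ci_high,
                 se = ci$se, auc_reps = auc_reps, probs = probs,
                 labels = y, n_pos = ci$n_pos, n_neg = ci$n_neg,
                 k = k, reps = reps),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), %dx%d-fold CV, %d pos / %d neg\n",
              x$auc, x$ci_low, x$ci_high, x$reps, x$k, x$n_pos, x$n_neg))
  invisible(x)
}

#' Optimize the probability threshold on an evaluation set
#'
#' Scans the midpoints between consecutive sorted unique probabilities
#' (plus 0.5) and returns the cut-point maximizing the objective on the
#' evaluation labels; ties break toward 0.5. Shifting the threshold on a
#' held-out evaluation set counters class imbalance without inflating
#' test-set performance.
#'
#' @param probs positive-class probabilities on the evaluation set.
#' @param labels evaluation labels (positive = second level).
#' @param objective `"balanced_accuracy"` (default) or `"youden"`.
#' @return threshold in (0, 1); the achieved objective is attached as
#'   attribute `objective_value`.
#' @export
optimize_threshold <- function(probs, labels,
                               objective = c("balanced_accuracy",
                                             "youden")) {
  objective <- match.arg(objective)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2)
    stop_bad_arg("evaluation labels have a single class")
  u <- sort(unique(probs))
  cand <- unique(c(if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, 0.5))
  obj <- vapply(cand, function(th) {
    cm <- confusion_metrics(probs, labels, th)
    if (objective == "balanced_accuracy") cm$balanced_accuracy
    else cm$sensitivity + cm$specificity - 1
  }, numeric(1))
  best <- obj >= max(obj) - 1e-12
  th <- cand[best][which.min(abs(cand[best] - 0.5))]
  attr(th, "objective_value") <- max(obj)
  th
}

#' Confusion-matrix metrics at a probability threshold
#'
#' Predictions are positive when `prob >= threshold`; the positive class
#' is the second label level (PPCS).
#'
#' @param probs positive-class probabilities.
#' @param labels binary factor.
#' @param threshold probability cut-point.
#' @return list `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `balanced_accuracy`, `accuracy`.
#' @export
confusion_metrics <- function(probs, labels, threshold = 0.5) {
  labels <- droplevels(as.factor(labels))
  pos <- levels(labels)[nlevels(labels)]
  is_pos <- labels == pos
  pred_pos <- probs >= threshold
  tp <- sum(pred_pos & is_pos); fp <- sum(pred_pos & !is_pos)
  tn <- sum(!pred_pos & !is_pos); fn <- sum(!pred_pos & is_pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = sens, specificity = spec,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       balanced_accuracy = (sens + spec) / 2,
       accuracy = (tp + tn) / length(probs))
}
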