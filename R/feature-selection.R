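#' Feature-selection configuration
#'
#' Knobs of the three-stream selection pipeline. Consensus and kappa
#' gates are strict inequalities: a feature appearing in exactly half of
#' the fold-lists is not selected, and a model with kappa exactly 0.20
#' contributes nothing.
#'
#' @param n_folds folds of the multifold selector.
#' @param learners subset of `random_forest`, `neural_net`.
#' @param top_k_per_fold features recorded per fold and learner.
#' @param consensus_fraction a feature must appear in strictly more than
#'   this fraction of fold x learner lists.
#' @param pearson_alpha unadjusted p cut of the numeric GLM stream.
#' @param kappa_min strict lower bound on cross-validated kappa for the
#'   binary GLM stream.
#' @param top_m_binary features contributed per qualifying binary
#'   response.
#' @param rfe_metric currently `balanced_accuracy` (cross-validated,
#'   of the downstream radial SVM) or `auc`.
#' @param rfe_cv_folds,rfe_cv_reps cross-validation scheme used to score
#'   panels during recursive feature elimination.
#' @param rf_num_trees,nnet_size,nnet_decay,nnet_maxit learner
#'   hyperparameters.
#' @param glmnet_alpha elastic-net mixing parameter of the penalized
#'   logistic stream.
#' @return a `selection_config` list.
#' @export
selection_config <- function(n_folds = 10L,
                             learners = c("random_forest", "neural_net"),
                             top_k_per_fold = 20L,
                             consensus_fraction = 0.5,
                             pearson_alpha = 0.05,
                             kappa_min = 0.20,
                             top_m_binary = 3L,
                             rfe_metric = c("balanced_accuracy", "auc"),
                             rfe_cv_folds = 5L, rfe_cv_reps = 1L,
                             rf_num_trees = 500L,
                             nnet_size = 3L, nnet_decay = 0.1,
                             nnet_maxit = 150L,
                             glmnet_alpha = 0.5) {
  learners <- match.arg(learners, several.ok = TRUE)
  if (n_folds < 2) stop_bad_arg("n_folds must be >= 2")
  structure(list(n_folds = as.integer(n_folds), learners = learners,
                 top_k_per_fold = as.integer(top_k_per_fold),
                 consensus_fraction = consensus_fraction,
                 pearson_alpha = pearson_alpha, kappa_min = kappa_min,
                 top_m_binary = as.integer(top_m_binary),
                 rfe_metric = match.arg(rfe_metric),
                 rfe_cv_folds = as.integer(rfe_cv_folds),
                 rfe_cv_reps = as.integer(rfe_cv_reps),
                 rf_num_trees = as.integer(rf_num_trees),
                 nnet_size = as.integer(nnet_size),
                 nnet_decay = nnet_decay,
                 nnet_maxit = as.integer(nnet_maxit),
                 glmnet_alpha = glmnet_alpha),
            class = "selection_config")
}

# Strict consensus rule: selected iff appearances / n_lists > fraction.
consensus_select <- function(appearances, n_lists, fraction = 0.5) {
  names(appearances)[appearances / n_lists > fraction]
}

learner_importance <- function(learner, x_tr, y_tr, x_ho, y_ho, cfg, seed) {
  if (learner == "random_forest") {
    fit <- ranger::ranger(x = x_tr, y = y_tr,
                          num.trees = cfg$rf_num_trees,
                          importance = "impurity",
                          num.threads = 1, seed = seed)
    return(fit$variable.importance)
  }
  # neural net: single hidden layer on standardized inputs; permutation
  # importance measured as held-out accuracy drop.
  mu <- colMeans(x_tr); sg <- apply(x_tr, 2, sd); sg[sg == 0] <- 1
  zs <- function(m) sweep(sweep(m, 2, mu), 2, sg, "/")
  xs <- zs(x_tr); xh <- zs(x_ho)
  withr::with_seed(seed, {
    fit <- nnet::nnet(xs, class.ind2(y_tr), size = cfg$nnet_size,
                      decay = cfg$nnet_decay, maxit = cfg$nnet_maxit,
                      softmax = TRUE, trace = FALSE,
                      MaxNWts = 100000)
    base <- mean(max.col(predict(fit, xh)) == as.integer(y_ho))
    imp <- vapply(seq_len(ncol(xh)), function(j) {
      xp <- xh
      xp[, j] <- sample(xp[, j])
      base - mean(max.col(predict(fit, xp)) == as.integer(y_ho))
    }, numeric(1))
  })
  names(imp) <- colnames(x_tr)
  imp
}

class.ind2 <- function(y) {
  y <- as.factor(y)
  m <- matrix(0, length(y), nlevels(y),
              dimnames = list(NULL, levels(y)))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

#' Multifold consensus feature selection
#'
#' For each of `n_folds` stratified folds, each learner is fit on the
#' fold's training part and its `top_k_per_fold` features by importance
#' are recorded (random forest: impurity importance; neural net:
#' permutation importance on the held-out part). A feature is selected
#' iff it appears in strictly more than `consensus_fraction` of the
#' fold x learner lists.
#'
#' @param X samples x features matrix.
#' @param y binary factor over samples.
#' @param cfg a [selection_config()].
#' @param seed integer seed.
#' @return list with `selected` (character), `appearances` (named
#'   counts), `n_lists`.
#' @export
multifold_select <- function(X, y, cfg = selection_config(), seed = 1L) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop_bad_arg("need at least 2 classes")
  if (cfg$top_k_per_fold > ncol(X))
    stop_bad_arg("top_k_per_fold exceeds the number of features")
  folds <- make_folds(y, cfg$n_folds, seed)
  lists <- list()
  for (f in seq_len(cfg$n_folds)) {
    tr <- folds != f
    for (ln in cfg$learners) {
      imp <- learner_importance(ln, X[tr, , drop = FALSE], y[tr],
                                X[!tr, , drop = FALSE], y[!tr],
                                cfg, seed + 97L * f)
      top <- names(sort(imp, decreasing = TRUE))[seq_len(cfg$top_k_per_fold)]
      lists[[paste(ln, f)]] <- top
    }
  }
  appearances <- table(unlist(lists))
  appearances <- setNames(as.integer(appearances), names(appearances))
  list(selected = consensus_select(appearances, length(lists),
                                   cfg$consensus_fraction),
       appearances = appearances, n_lists = length(lists))
}

#' Numeric-response GLM stream
#'
#' Union over responses of features with unadjusted Pearson p strictly
#' below `alpha` (linear-association screen; delegates to
#' [pearson_scan()]).
#'
#' @param X samples x features matrix.
#' @param responses named list of numeric response vectors.
#' @param alpha unadjusted significance cut (default 0.05).
#' @return character vector of selected feature ids; per-response hits
#'   in attribute `by_response`.
#' @export
glm_stream_numeric <- function(X, responses, alpha = 0.05) {
  hits <- list()
  for (nm in names(responses)) {
    y <- responses[[nm]]
    if (sd(y) == 0) {
      warning("response '", nm, "' has zero variance; skipped",
              call. = FALSE)
      next
    }
    sc <- pearson_scan(X, y, alpha)
    hits[[nm]] <- sc$feature_id[!sc$flagged & sc$p_value < alpha]
  }
  out <- unique(as.character(unlist(hits)))
  attr(out, "by_response") <- hits
  out
}

# Cross-validated kappa of a penalized logistic model at a fixed lambda.
cv_glmnet_kappa <- function(X, y, lambda, alpha, seed, k = 5L) {
  folds <- make_folds(y, k, seed)
  pred <- character(length(y))
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
                          family = "binomial", alpha = alpha,
                          lambda = lambda)
    pr <- predict(fit, X[!tr, , drop = FALSE], type = "class", s = lambda)
    pred[!tr] <- pr
  }
  cohen_kappa(pred, y)
}

#' Binary-response GLM stream
#'
#' For each binary response a penalized logistic model is fit (glmnet;
#' lambda chosen by internal cross-validation). If the model's
#' cross-validated Cohen's kappa is strictly greater than
#' `cfg$kappa_min`, the response contributes its `cfg$top_m_binary`
#' features by absolute standardized coefficient; otherwise nothing.
#'
#' @param X samples x features matrix.
#' @param responses named list of binary responses (factor or 0/1).
#' @param cfg a [selection_config()].
#' @param seed integer seed.
#' @param .kappa_fun kappa evaluator, injectable for boundary testing;
#'   signature `(X, y, lambda, alpha, seed)`.
#' @return character vector of selected features; per-response detail in
#'   attribute `by_response`.
#' @export
glm_stream_binary <- function(X, responses, cfg = selection_config(),
                              seed = 1L, .kappa_fun = cv_glmnet_kappa) {
  X <- as.matrix(X)
  hits <- list()
  for (nm in names(responses)) {
    y <- droplevels(as.factor(responses[[nm]]))
    if (nlevels(y) < 2 || min(table(y)) < 3) {
      warning("response '", nm, "' lacks both classes; skipped",
              call. = FALSE)
      next
    }
    cv <- withr::with_seed(seed, glmnet::cv.glmnet(
      X, y, family = "binomial", alpha = cfg$glmnet_alpha, nfolds = 5))
    lam <- cv$lambda.min
    kappa <- .kappa_fun(X, y, lam, cfg$glmnet_alpha, seed)
    if (!(kappa > cfg$kappa_min)) next  # strict gate
    cf <- as.matrix(coef(cv, s = lam))[-1, 1]
    std <- abs(cf) * apply(X, 2, sd)
    top <- names(sort(std, decreasing = TRUE))
    top <- top[std[top] > 0]
    hits[[nm]] <- head(top, cfg$top_m_binary)
  }
  out <- unique(as.character(unlist(hits)))
  attr(out, "by_response") <- hits
  out
}

#' Combine selection streams into a candidate feature panel
#'
#' Set union of the streams with per-feature provenance. A
#' differential-expression result data.frame may be passed for `de`, in
#' which case its features with `padj < 0.05` contribute.
#'
#' @param multifold,de,glm_numeric,glm_binary character vectors of
#'   feature ids (or, for `de`, a [nb_wald_test()] data.frame).
#' @param de_fdr FDR cut applied when `de` is a data.frame.
#' @return a `feature_panel` data.frame: `feature_id`, `provenance`
#'   (comma-separated stream names).
#' @export
union_candidates <- function(multifold = NULL, de = NULL,
                             glm_numeric = NULL, glm_binary = NULL,
                             de_fdr = 0.05) {
  if (is.data.frame(de)) de <- de$feature_id[de$padj < de_fdr]
  streams <- list(multifold = multifold, de = de,
                  glm_numeric = glm_numeric, glm_binary = glm_binary)
  streams <- lapply(streams, function(s) unique(as.character(s)))
  all_ids <- unique(unlist(streams))
  if (length(all_ids) == 0)
    stop_bad_arg("no candidate features selected by any stream; ",
                 "relax the stream thresholds")
  prov <- vapply(all_ids, function(id)
    paste(names(streams)[vapply(streams, function(s) id %in% s,
                                logical(1))], collapse = ","),
    character(1))
  out <- data.frame(feature_id = all_ids, provenance = unname(prov),
                    stringsAsFactors = FALSE)
  class(out) <- c("feature_panel", class(out))
  out
}

panel_ids <- function(panel) {
  if (is.data.frame(panel)) panel$feature_id else as.character(panel)
}

# Cross-validated panel score used by RFE: balanced accuracy (or AUC) of
# the downstream radial SVM under a fixed fold assignment, so panel
# comparisons are paired.
rfe_panel_score <- function(X, y, features, folds, metric) {
  probs <- numeric(length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- e1071::svm(X[tr, features, drop = FALSE], y[tr],
                      kernel = "radial", probability = TRUE, scale = TRUE)
    pr <- predict(fit, X[!tr, features, drop = FALSE], probability = TRUE)
    probs[!tr] <- attr(pr, "probabilities")[, levels(y)[2]]
  }
  if (metric == "auc") return(auc_mann_whitney(probs, y))
  pred <- ifelse(probs >= 0.5, levels(y)[2], levels(y)[1])
  balanced_accuracy(pred, y, positive = levels(y)[2])
}

#' Recursive feature elimination
#'
#' Backward elimination: at each step the cross-validated performance of
#' every single-feature omission is evaluated, and the feature whose
#' omission maximizes performance is removed; elimination stops when no
#' omission strictly improves on the best performance seen so far. The
#' panel at the best-performing step is returned with the full trace.
#'
#' @param X samples x features matrix.
#' @param y binary factor.
#' @param panel a `feature_panel` or character vector (subset of
#'   `colnames(X)`).
#' @param cfg a [selection_config()].
#' @param seed integer seed (fixes the CV folds for all comparisons).
#' @return list with `panel` (character), `trace` (data.frame `step`,
#'   `n_features`, `removed`, `score`).
#' @export
rfe <- function(X, y, panel, cfg = selection_config(), seed = 1L) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  feats <- panel_ids(panel)
  if (length(feats) == 0) stop_bad_arg("panel is empty")
  if (!all(feats %in% colnames(X)))
    stop_bad_arg("panel contains features absent from X")
  folds <- make_folds(y, cfg$rfe_cv_folds, seed)
  current <- feats
  best_score <- rfe_panel_score(X, y, current, folds, cfg$rfe_metric)
  best_panel <- current
  trace <- data.frame(step = 0L, n_features = length(current),
                      removed = NA_character_, score = best_score,
                      stringsAsFactors = FALSE)
  step <- 0L
  while (length(current) > 1) {
    scores <- vapply(current, function(f)
      rfe_panel_score(X, y, setdiff(current, f), folds, cfg$rfe_metric),
      numeric(1))
    cand <- names(scores)[order(-scores, names(scores))][1]
    if (!(scores[cand] > best_score)) break
    current <- setdiff(current, cand)
    best_score <- scores[cand]
    best_panel <- current
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step,
                                     n_features = length(current),
                                     removed = cand,
                                     score = best_score,
                                     stringsAsFactors = FALSE))
  }
  list(panel = best_panel, trace = trace)
}

#' Gradient-boosted importance ranking of a final panel
#'
#' Fits boosted trees on the panel features and orders them by total
#' split-gain importance; features never used in a split get gain 0,
#' and ties break lexicographically.
#'
#' @param X samples x features matrix.
#' @param y binary factor.
#' @param panel panel to rank (subset of `colnames(X)`).
#' @param seed integer seed.
#' @param nrounds,max_depth,eta boosting hyperparameters.
#' @return data.frame `feature_id`, `gain`, `rank` (a permutation of the
#'   input panel).
#' @export
gbm_rank <- function(X, y, panel, seed = 1L, nrounds = 100L,
                     max_depth = 3L, eta = 0.1) {
  feats <- panel_ids(panel)
  if (length(feats) == 0) stop_bad_arg("panel is empty")
  y <- droplevels(as.factor(y))
  Xp <- as.matrix(X[, feats, drop = FALSE])
  withr::with_seed(seed, {
    fit <- xgboost::xgboost(Xp, y, nrounds = nrounds,
                            max_depth = max_depth, learning_rate = eta,
                            nthread = 1, verbosity = 0)
  })
  imp <- tryCatch(xgboost::xgb.importance(model = fit),
                  error = function(e) NULL)
  gain <- setNames(rep(0, length(feats)), feats)
  if (!is.null(imp)) gain[imp$Feature] <- imp$Gain
  ord <- order(-gain, names(gain))
  data.frame(feature_id = names(gain)[ord], gain = unname(gain)[ord],
             rank = seq_along(gain), stringsAsFactors = FALSE)
}

#' Run the full three-stream selection pipeline on training data
#'
#' Multifold consensus + differential expression + the two penalized-GLM
#' streams, union, recursive feature elimination, and gradient-boosted
#' ranking. All inputs must come from the training split only.
#'
#' @param X training samples x features matrix (normalized).
#' @param y training binary factor (PPCS status).
#' @param counts training [ncrna_counts()] for the DE stream (optional;
#'   the DE stream is skipped when NULL).
#' @param numeric_responses,binary_responses named lists of training
#'   response vectors for the GLM streams.
#' @param cfg a [selection_config()].
#' @param seed integer seed.
#' @return list with `panel` (ranked data.frame), `candidates`
#'   (the pre-RFE `feature_panel`), `rfe_trace`, `streams`.
#' @export
select_features <- function(X, y, counts = NULL,
                            numeric_responses = list(),
                            binary_responses = list(),
                            cfg = selection_config(), seed = 1L) {
  mf <- multifold_select(X, y, cfg, seed)
  de <- if (!is.null(counts)) nb_wald_test(counts, y) else NULL
  gn <- if (length(numeric_responses))
    glm_stream_numeric(X, numeric_responses, cfg$pearson_alpha) else NULL
  gb <- if (length(binary_responses))
    glm_stream_binary(X, binary_responses, cfg, seed) else NULL
  candidates <- union_candidates(multifold = mf$selected, de = de,
                                 glm_numeric = gn, glm_binary = gb)
  reduced <- rfe(X, y, candidates, cfg, seed)
  ranked <- gbm_rank(X, y, reduced$panel, seed)
  list(panel = ranked, candidates = candidates,
       rfe_trace = reduced$trace,
       streams = list(multifold = mf, de = de, glm_numeric = gn,
                      glm_binary = gb))
}
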