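#' @import stats
#' @importFrom utils head read.csv write.csv read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(...) stop(..., call. = FALSE)

#' Stratified cross-validation fold assignment
#'
#' Assigns each sample to one of `k` folds, keeping class proportions as
#' even as integer arithmetic allows. Deterministic given `seed`.
#'
#' @param y factor (or coercible) of class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1:k`, same length as `y`.
#' @export
make_folds <- function(y, k, seed = 1L) {
  y <- as.factor(y)
  if (k < 2) stop_bad_arg("k must be >= 2")
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Balanced accuracy of a binary prediction
#'
#' @param pred,obs vectors of predicted and observed labels.
#' @param positive the positive-class label (default: second factor level
#'   of `obs`).
#' @return mean of sensitivity and specificity.
#' @export
balanced_accuracy <- function(pred, obs, positive = NULL) {
  obs <- as.factor(obs)
  positive <- positive %||% levels(obs)[nlevels(obs)]
  is_pos <- obs == positive
  sens <- mean(pred[is_pos] == positive)
  spec <- mean(pred[!is_pos] != positive)
  (sens + spec) / 2
}

#' Cohen's kappa for two label vectors
#'
#' Chance-corrected agreement; the "fair"-accuracy gate of the binary GLM
#' selection stream uses the conventional kappa > 0.20 cut.
#'
#' @param pred,obs label vectors of equal length.
#' @return kappa in \[-1, 1\] (0 when chance agreement is exact).
#' @export
cohen_kappa <- function(pred, obs) {
  lev <- union(as.character(pred), as.character(obs))
  pred <- factor(as.character(pred), levels = lev)
  obs <- factor(as.character(obs), levels = lev)
  tab <- table(pred, obs) / length(pred)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (abs(1 - pe) < .Machine$double.eps) return(0)
  (po - pe) / (1 - pe)
}

# Age bins used for split stratification and the Zemek age predictor:
# 8-12, 13-18, 19-24 (Zemek child/adolescent bins plus the adult extension).
age_bin <- function(age) {
  cut(age, breaks = c(-Inf, 12, 18, Inf), labels = c("8-12", "13-18", "19-24"))
}
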