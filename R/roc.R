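#' Mann-Whitney AUC estimator
#'
#' The probability that a random positive outscores a random negative,
#' with half credit for ties; computed from rank sums, which equals the
#' normalized Mann-Whitney U and the pair-counting estimator.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels; the positive class is the second factor
#'   level (or `positive`).
#' @param positive optional positive-class label.
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores, labels, positive = NULL) {
  labels <- as.factor(labels)
  positive <- positive %||% levels(labels)[nlevels(labels)]
  is_pos <- labels == positive
  m <- sum(is_pos); n <- sum(!is_pos)
  if (m == 0 || n == 0) stop_bad_arg("both classes must be present")
  r <- rank(scores)
  (sum(r[is_pos]) - m * (m + 1) / 2) / (m * n)
}

# DeLong placement values: V10[i] = fraction of negatives below positive
# i (half credit at ties); V01[j] symmetrically.
delong_placements <- function(scores, is_pos) {
  x <- scores[is_pos]; yv <- scores[!is_pos]
  m <- length(x); n <- length(yv)
  v10 <- vapply(x, function(xi)
    (sum(yv < xi) + 0.5 * sum(yv == xi)) / n, numeric(1))
  v01 <- vapply(yv, function(yj)
    (sum(x > yj) + 0.5 * sum(x == yj)) / m, numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' DeLong confidence interval for one AUC
#'
#' Nonparametric variance of the Mann-Whitney AUC from placement-value
#' (structural-component) variances; CI is `auc +/- z * SE`, clamped to
#' \[0, 1\].
#'
#' @inheritParams auc_mann_whitney
#' @param level confidence level (default 0.95).
#' @return list `auc`, `se`, `ci_low`, `ci_high`, `n_pos`, `n_neg`.
#' @export
delong_ci <- function(scores, labels, positive = NULL, level = 0.95) {
  labels <- as.factor(labels)
  positive <- positive %||% levels(labels)[nlevels(labels)]
  is_pos <- labels == positive
  if (!any(is_pos) || all(is_pos))
    stop_bad_arg("both classes must be present")
  pl <- delong_placements(scores, is_pos)
  se <- sqrt(var(pl$v10) / pl$m + var(pl$v01) / pl$n)
  z <- qnorm(1 - (1 - level) / 2)
  list(auc = pl$auc, se = se,
       ci_low = max(0, pl$auc - z * se),
       ci_high = min(1, pl$auc + z * se),
       n_pos = pl$m, n_neg = pl$n)
}

#' DeLong test comparing two correlated ROC curves
#'
#' Both score vectors must be computed on the same samples (paired
#' design). The variance of the AUC difference includes the covariance
#' of the placement values, and the two-sided p-value is normal.
#'
#' @param scores_a,scores_b paired score vectors.
#' @inheritParams auc_mann_whitney
#' @param level confidence level of the difference CI.
#' @return list `auc_a`, `auc_b`, `auc_diff`, `se`, `z`, `p_value`,
#'   `ci_low`, `ci_high`.
#' @export
delong_test <- function(scores_a, scores_b, labels, positive = NULL,
                        level = 0.95) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop_bad_arg("scores_a, scores_b and labels must be paired ",
                 "(equal length)")
  labels <- as.factor(labels)
  positive <- positive %||% levels(labels)[nlevels(labels)]
  is_pos <- labels == positive
  pa <- delong_placements(scores_a, is_pos)
  pb <- delong_placements(scores_b, is_pos)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
        (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
  diff <- pa$auc - pb$auc
  se <- sqrt(max(vd, 0))
  z <- if (se == 0) 0 else diff / se
  zq <- qnorm(1 - (1 - level) / 2)
  list(auc_a = pa$auc, auc_b = pb$auc, auc_diff = diff, se = se, z = z,
       p_value = if (se == 0 && diff == 0) 1 else 2 * pnorm(-abs(z)),
       ci_low = diff - zq * se, ci_high = diff + zq * se)
}

hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Power of a two-sided z-test comparing an AUC to a null value
#'
#' Hanley-McNeil (binormal-ratings) standard errors at the null and
#' alternative AUCs; power accumulates both rejection tails:
#' `power = Phi((A1 - A0 - z * SE0) / SE1) +
#'          Phi((A0 - A1 - z * SE0) / SE1)`
#' with `z` the two-sided critical value at level `alpha`. At
#' `A1 = A0` the power equals `alpha`.
#'
#' @param null_auc,alt_auc null and alternative AUCs, each in
#'   \[0.5, 1).
#' @param n_pos,n_neg class sample sizes.
#' @param alpha two-sided significance level (default 0.05).
#' @return power in \[0, 1\].
#' @export
auc_power <- function(null_auc, alt_auc, n_pos, n_neg, alpha = 0.05) {
  for (a in c(null_auc, alt_auc))
    if (a < 0.5 || a >= 1)
      stop_bad_arg("AUCs must be in [0.5, 1)")
  if (n_pos < 2 || n_neg < 2) stop_bad_arg("need n_pos, n_neg >= 2")
  se0 <- hanley_mcneil_se(null_auc, n_pos, n_neg)
  se1 <- hanley_mcneil_se(alt_auc, n_pos, n_neg)
  z <- qnorm(1 - alpha / 2)
  pnorm((alt_auc - null_auc - z * se0) / se1) +
    pnorm((null_auc - alt_auc - z * se0) / se1)
}
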