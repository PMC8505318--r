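#' The 22 PCSS items and their symptom categories
#'
#' Read from the editable data file shipped with the package:
#' 10 physical, 4 cognitive, 4 emotional, 4 sleep items.
#'
#' @return data.frame with columns `item`, `category`.
#' @export
pcss_items <- function() {
  read.csv(system.file("extdata", "pcss_categories.csv",
                       package = "ppcsrna"),
           stringsAsFactors = FALSE)
}

#' PCSS total and normalized category scores
#'
#' The total is the sum of the 22 items (0-132). Category scores are
#' per-item means within each category, which normalizes for the unequal
#' numbers of items per category.
#'
#' @param report numeric vector of 22 item scores in 0-6, in the
#'   canonical [pcss_items()] order, or named by item.
#' @return list with `total` and `categories` (named numeric of per-item
#'   category means).
#' @export
pcss_score <- function(report) {
  map <- pcss_items()
  if (!is.null(names(report))) {
    miss <- setdiff(map$item, names(report))
    if (length(miss))
      stop_bad_arg("missing items: ", paste(head(miss), collapse = ", "))
    report <- report[map$item]
  }
  if (length(report) != nrow(map))
    stop_bad_arg("report must have ", nrow(map), " items")
  if (any(is.na(report)) || any(report < 0 | report > 6))
    stop_bad_arg("item scores must be in 0-6")
  cats <- split(as.numeric(report), map$category)
  list(total = sum(report),
       categories = vapply(cats, mean, numeric(1)))
}

#' Default modified Zemek scoring table
#'
#' Loads the editable YAML shipped with the package: nine predictors,
#' each worth 0-2 points, maximum 12. Ages above the published 5-18
#' range score 0 on the age predictor; PCSS-item predictors count as
#' present at item score >= 1.
#'
#' @return list with `item_present_min` and named `points`.
#' @export
zemek_default_table <- function() {
  yaml::read_yaml(system.file("extdata", "zemek_scoring.yaml",
                              package = "ppcsrna"))
}

#' Modified Zemek 12-point PPCS risk score
#'
#' Sums the points of the nine satisfied predictors: age group, sex,
#' prior concussion with symptoms lasting at least a week, migraine
#' history, and the five PCSS-item surrogates (feeling slowed down,
#' balance problems, headache, sensitivity to noise, fatigue). Missing
#' optional fields (prior symptom duration, migraine history) score 0
#' with a warning; missing sex or age is an error.
#'
#' @param participant list or one-row data.frame with `sex` ("F"/"M"),
#'   `age`, `prior_concussions`, `prior_symptom_duration_days`,
#'   `migraine_history`.
#' @param report PCSS item vector (named, or canonical order).
#' @param table scoring table (default [zemek_default_table()]).
#' @return integer risk score in 0-12.
#' @export
zemek_risk_score <- function(participant, report,
                             table = zemek_default_table()) {
  pt <- table$points
  p <- as.list(participant)
  if (is.null(p$sex) || is.na(p$sex)) stop_bad_arg("sex is required")
  if (is.null(p$age) || is.na(p$age)) stop_bad_arg("age is required")
  map <- pcss_items()
  if (is.null(names(report))) {
    if (length(report) != nrow(map))
      stop_bad_arg("report must have ", nrow(map), " items")
    names(report) <- map$item
  }
  present <- function(item) {
    v <- report[[item]]
    if (is.null(v) || is.na(v)) {
      warning("PCSS item '", item, "' missing; scored 0", call. = FALSE)
      return(FALSE)
    }
    v >= table$item_present_min
  }
  score <- 0L
  if (p$sex == "F") score <- score + pt$female
  score <- score + if (p$age <= 12) pt$age_8_12
    else if (p$age <= 18) pt$age_13_18 else pt$age_over_18
  prior <- p$prior_concussions %||% 0
  dur <- p$prior_symptom_duration_days
  if (!is.na(prior) && prior >= 1) {
    if (is.null(dur) || is.na(dur)) {
      warning("prior symptom duration missing; prior-concussion ",
              "predictor scored 0", call. = FALSE)
    } else if (dur >= 7) {
      score <- score + pt$prior_concussion_symptoms_ge_1wk
    }
  }
  mig <- p$migraine_history
  if (is.null(mig) || is.na(mig)) {
    warning("migraine history missing; scored 0", call. = FALSE)
  } else if (isTRUE(as.logical(mig))) {
    score <- score + pt$migraine_history
  }
  for (item in c("feeling_slowed_down", "balance_problems", "headache",
                 "sensitivity_to_noise", "fatigue"))
    if (present(item)) score <- score + pt[[item]]
  as.integer(score)
}

#' Zemek predictor point contributions as a feature vector
#'
#' The nine per-predictor point contributions (used as the feature set
#' of the clinical-comparator classifier).
#'
#' @inheritParams zemek_risk_score
#' @return named numeric vector of nine point contributions.
#' @export
zemek_features <- function(participant, report,
                           table = zemek_default_table()) {
  pt <- table$points
  p <- as.list(participant)
  map <- pcss_items()
  if (is.null(names(report))) names(report) <- map$item
  pres <- function(item) {
    v <- report[[item]]
    !is.null(v) && !is.na(v) && v >= table$item_present_min
  }
  prior <- p$prior_concussions %||% 0
  dur <- p$prior_symptom_duration_days
  c(age = if (p$age <= 12) pt$age_8_12
      else if (p$age <= 18) pt$age_13_18 else pt$age_over_18,
    sex = if (p$sex == "F") pt$female else 0,
    prior_concussion = if (!is.na(prior) && prior >= 1 && !is.null(dur) &&
                           !is.na(dur) && dur >= 7)
      pt$prior_concussion_symptoms_ge_1wk else 0,
    migraine = if (isTRUE(as.logical(p$migraine_history)))
      pt$migraine_history else 0,
    slowed = if (pres("feeling_slowed_down")) pt$feeling_slowed_down else 0,
    balance = if (pres("balance_problems")) pt$balance_problems else 0,
    headache = if (pres("headache")) pt$headache else 0,
    noise = if (pres("sensitivity_to_noise")) pt$sensitivity_to_noise else 0,
    fatigue = if (pres("fatigue")) pt$fatigue else 0)
}

#' Minimal detectable change from test-retest reliability
#'
#' `SEM = sd_baseline * sqrt(1 - ICC)`;
#' `MDC95 = 1.96 * sqrt(2) * SEM`, the 95% band of random
#' measurement error for a change score.
#'
#' @param sd_baseline baseline between-subject standard deviation.
#' @param icc test-retest intraclass correlation in \[0, 1\].
#' @return an `mdc` list with `sem` and `mdc95`.
#' @export
compute_mdc <- function(sd_baseline, icc) {
  if (sd_baseline < 0) stop_bad_arg("sd_baseline must be >= 0")
  if (icc < 0 || icc > 1) stop_bad_arg("icc must be in [0, 1]")
  sem <- sd_baseline * sqrt(1 - icc)
  structure(list(sem = sem, mdc95 = 1.96 * sqrt(2) * sem), class = "mdc")
}

#' Classify a score change against the minimal detectable change
#'
#' A change within `mdc95` in absolute value is `unchanged`; larger
#' changes are `improved` or `worsened` according to the direction
#' convention (lower = better by default, matching sway and reaction
#' time).
#'
#' @param initial,followup scores at the two time points.
#' @param mdc a [compute_mdc()] result (or numeric mdc95).
#' @param better `"lower"` (default) or `"higher"`.
#' @return one of `"improved"`, `"unchanged"`, `"worsened"`.
#' @export
mdc_change <- function(initial, followup, mdc, better = c("lower", "higher")) {
  better <- match.arg(better)
  mdc95 <- if (inherits(mdc, "mdc")) mdc$mdc95 else as.numeric(mdc)
  delta <- followup - initial
  if (abs(delta) <= mdc95) return("unchanged")
  if ((delta < 0) == (better == "lower")) "improved" else "worsened"
}

#' Two-group comparison (t, Mann-Whitney, or Yates chi-squared)
#'
#' Continuous comparisons are unpaired Welch t or Mann-Whitney tests on
#' two vectors; nominal comparisons are Yates-corrected chi-squared
#' tests, statistic `sum((|O - E| - 0.5)^2 / E)` with df = 1, on a 2x2
#' table.
#'
#' @param a numeric vector (or a 2x2 table for the chi-squared kind).
#' @param b numeric vector (ignored for the chi-squared kind).
#' @param kind test to run.
#' @return list with `statistic`, `p_value`, `method`.
#' @export
compare_groups <- function(a, b = NULL,
                           kind = c("continuous_t", "continuous_mw",
                                    "nominal_chi2_yates")) {
  kind <- match.arg(kind)
  res <- switch(kind,
    continuous_t = t.test(a, b),
    continuous_mw = wilcox.test(a, b, exact = FALSE),
    nominal_chi2_yates = {
      tab <- as.matrix(a)
      if (!all(dim(tab) == c(2, 2)))
        stop_bad_arg("Yates chi-squared needs a 2x2 table")
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected == 0)) stop_bad_arg("expected cell count of 0")
      chisq.test(tab, correct = TRUE)
    })
  list(statistic = unname(res$statistic), p_value = res$p.value,
       method = res$method)
}
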