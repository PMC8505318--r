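#' Derive the PPCS symptom threshold from control scores
#'
#' The threshold is the smallest integer strictly above the upper 95%
#' confidence limit of the mean control PCSS total,
#' `mean + 1.96 * sd / sqrt(n)` (normal approximation). With the
#' reference control summary (mean 3.5, sd 4, n 170) the upper limit is
#' 4.10 and the integer threshold 5.
#'
#' @param control_scores integer vector of PCSS totals from non-injured
#'   controls (n >= 2).
#' @return a `ppcs_threshold` list: `control_mean`, `control_sd`,
#'   `control_n`, `upper_ci`, `integer_threshold`.
#' @export
derive_ppcs_threshold <- function(control_scores) {
  n <- length(control_scores)
  if (n < 2) stop_bad_arg("need at least 2 control scores (sd undefined)")
  ppcs_threshold_from_summary(mean(control_scores), sd(control_scores), n)
}

#' @param control_mean,control_sd,control_n control summary statistics
#'   (usable directly when only the published summary is available).
#' @rdname derive_ppcs_threshold
#' @export
ppcs_threshold_from_summary <- function(control_mean, control_sd,
                                        control_n) {
  if (control_n < 2) stop_bad_arg("control_n must be >= 2")
  if (control_sd < 0) stop_bad_arg("control_sd must be >= 0")
  upper <- control_mean + 1.96 * control_sd / sqrt(control_n)
  structure(list(control_mean = control_mean, control_sd = control_sd,
                 control_n = control_n, upper_ci = upper,
                 integer_threshold = as.integer(floor(upper) + 1)),
            class = "ppcs_threshold")
}

#' @export
print.ppcs_threshold <- function(x, ...) {
  cat(sprintf(
    "PPCS threshold: %d (upper 95%% CI of control mean = %.3f; n = %d)\n",
    x$integer_threshold, x$upper_ci, x$control_n))
  invisible(x)
}

as_threshold_int <- function(threshold) {
  if (inherits(threshold, "ppcs_threshold")) threshold$integer_threshold
  else as.numeric(threshold)
}

#' Assign PPCS labels from longitudinal symptom reports
#'
#' A participant is labeled PPCS iff the PCSS total of their earliest
#' report at or after `followup_min_days` post-injury meets or exceeds
#' the integer threshold. Participants with no report in the follow-up
#' window are excluded with a reason code.
#'
#' @param samples data.frame with `participant_id`, `sample_id`,
#'   `days_post_injury`, `pcss_total` (e.g. `cohort$samples`).
#' @param threshold a [derive_ppcs_threshold()] result or an integer.
#' @param followup_min_days first day counted as follow-up (default 21).
#' @return list with `labels` (data.frame `participant_id`, `label`
#'   factor non-PPCS/PPCS, `labeling_sample_id`, `labeling_total`) and
#'   `excluded` (data.frame `participant_id`, `reason`).
#' @export
assign_ppcs <- function(samples, threshold, followup_min_days = 21) {
  thr <- as_threshold_int(threshold)
  out <- lapply(split(samples, samples$participant_id), function(d) {
    d <- d[d$days_post_injury >= followup_min_days, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    d <- d[order(d$days_post_injury), , drop = FALSE]
    data.frame(participant_id = d$participant_id[1],
               label = if (d$pcss_total[1] >= thr) "PPCS" else "non-PPCS",
               labeling_sample_id = d$sample_id[1],
               labeling_total = d$pcss_total[1],
               stringsAsFactors = FALSE)
  })
  labeled <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(labeled))
    stop_bad_arg("no participant has a follow-up report")
  excl_ids <- setdiff(unique(samples$participant_id),
                      labeled$participant_id)
  excluded <- data.frame(
    participant_id = excl_ids,
    reason = rep("no_followup_report", length(excl_ids)),
    stringsAsFactors = FALSE)
  labeled$label <- factor(labeled$label, levels = c("non-PPCS", "PPCS"))
  rownames(labeled) <- NULL
  list(labels = labeled, excluded = excluded)
}

#' Stratified training / evaluation / testing split
#'
#' Samples are stratified by (age bin, sex, PPCS label) and allocated to
#' the three sets by largest-remainder rounding within each stratum, so
#' class and demographic proportions are equal across sets up to
#' rounding. At most `max_per_participant` samples of any participant
#' may sit in the training set, and likewise in the testing set; excess
#' samples are moved to the evaluation set. Deterministic given `seed`.
#'
#' @param samples data.frame with `sample_id`, `participant_id`, `age`,
#'   `sex`, `label`.
#' @param fractions named numeric vector over
#'   `training`/`evaluation`/`testing`, summing to 1.
#' @param seed integer seed.
#' @param max_per_participant per-participant cap for training and
#'   testing (default 5).
#' @return data.frame `sample_id`, `participant_id`, `set` (factor);
#'   a `table(set, label)` tally is attached as attribute `tallies`.
#' @export
split_samples <- function(samples,
                          fractions = c(training = 0.58, evaluation = 0.23,
                                        testing = 0.19),
                          seed = 1L, max_per_participant = 5L) {
  if (abs(sum(fractions) - 1) > 1e-8)
    stop_bad_arg("fractions must sum to 1")
  sets <- c("training", "evaluation", "testing")
  if (!all(sets %in% names(fractions)))
    stop_bad_arg("fractions must be named training/evaluation/testing")
  if (length(unique(samples$label)) < 2)
    stop_bad_arg("need both classes present")
  strat <- interaction(age_bin(samples$age), samples$sex, samples$label,
                       drop = TRUE)
  assign <- character(nrow(samples))
  withr::with_seed(seed, {
    for (g in levels(strat)) {
      idx <- sample(which(strat == g))
      sizes <- largest_remainder(length(idx), fractions[sets])
      assign[idx] <- rep(sets, sizes)
    }
    # enforce the per-participant cap in training and testing
    for (st in c("training", "testing")) {
      tab <- table(samples$participant_id[assign == st])
      for (p in names(tab[tab > max_per_participant])) {
        idx <- which(assign == st & samples$participant_id == p)
        move <- sample(idx, length(idx) - max_per_participant)
        assign[move] <- "evaluation"
      }
    }
  })
  out <- data.frame(sample_id = samples$sample_id,
                    participant_id = samples$participant_id,
                    set = factor(assign, levels = sets),
                    stringsAsFactors = FALSE)
  attr(out, "tallies") <- table(set = out$set, label = samples$label)
  attr(out, "seed") <- seed
  out
}

#' Drop samples with PCSS totals near the PPCS threshold
#'
#' Removes samples whose total is within `margin` points of the integer
#' threshold (|total - threshold| <= margin), increasing the fidelity of
#' recovered / not-recovered group assignment.
#'
#' @param samples data.frame with a `pcss_total` column.
#' @param threshold a [derive_ppcs_threshold()] result or integer.
#' @param margin half-width of the exclusion band (default 2).
#' @return filtered data.frame; removal count in attribute `n_removed`.
#' @export
filter_near_threshold <- function(samples, threshold, margin = 2) {
  thr <- as_threshold_int(threshold)
  keep <- abs(samples$pcss_total - thr) > margin
  out <- samples[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}
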