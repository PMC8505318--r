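#' Configuration of the end-to-end experiments
#'
#' @param sim a [sim_config()] describing the (synthetic) cohort.
#' @param selection a [selection_config()].
#' @param split_fractions training/evaluation/testing fractions.
#' @param svm_hyperparams radial-SVM hyperparameters.
#' @param cv_k,cv_reps repeated cross-validation scheme for the model
#'   comparisons.
#' @param threshold_objective objective of evaluation-set threshold
#'   tuning.
#' @param identity_threshold,min_fraction preprocessing knobs.
#' @param near_threshold_margin PCSS exclusion band of the recovery
#'   experiment.
#' @param run_selection logical; FALSE uses the full feature set (stage
#'   toggle).
#' @param seed global seed.
#' @return a `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       selection = selection_config(),
                       split_fractions = c(training = 0.58,
                                           evaluation = 0.23,
                                           testing = 0.19),
                       svm_hyperparams = list(cost = 1),
                       cv_k = 10L, cv_reps = 10L,
                       threshold_objective = "balanced_accuracy",
                       identity_threshold = 0.90, min_fraction = 1e-4,
                       near_threshold_margin = 2,
                       run_selection = TRUE,
                       seed = 1L) {
  structure(list(sim = sim, selection = selection,
                 split_fractions = split_fractions,
                 svm_hyperparams = svm_hyperparams,
                 cv_k = as.integer(cv_k), cv_reps = as.integer(cv_reps),
                 threshold_objective = threshold_objective,
                 identity_threshold = identity_threshold,
                 min_fraction = min_fraction,
                 near_threshold_margin = near_threshold_margin,
                 run_selection = isTRUE(run_selection),
                 seed = as.integer(seed)),
            class = "run_config")
}

# Shared staging: simulate (unless provided), preprocess, label, and
# attach per-sample metadata. Returns everything downstream stages need.
stage_inputs <- function(config, cohort = NULL, counts = NULL) {
  cohort <- cohort %||%
    simulate_functional_scores(generate_cohort(config$sim), config$sim)
  counts <- counts %||% simulate_counts(cohort, config$sim)
  pre <- preprocess_counts(counts,
                           identity_threshold = config$identity_threshold,
                           min_fraction = config$min_fraction)
  thr <- ppcs_threshold_from_summary(config$sim$control_mean,
                                     config$sim$control_sd,
                                     config$sim$control_n)
  lab <- assign_ppcs(cohort$samples, thr,
                     config$sim$followup_min_days)
  meta <- merge(cohort$samples,
                cohort$participants[, c("participant_id", "age", "sex",
                                        "prior_concussions",
                                        "prior_symptom_duration_days",
                                        "migraine_history")],
                by = "participant_id", sort = FALSE)
  meta <- merge(meta, lab$labels[, c("participant_id", "label")],
                by = "participant_id", sort = FALSE)
  list(cohort = cohort, counts = counts, pre = pre, threshold = thr,
       labels = lab, meta = meta)
}

sample_feature_matrix <- function(pre, meta, extra = "age") {
  X <- t(pre$matrix)[meta$sample_id, , drop = FALSE]
  for (e in extra) X <- cbind(X, setNames(meta[e], e))
  as.matrix(X)
}

zemek_feature_matrix <- function(meta) {
  items <- pcss_items()$item
  t(vapply(seq_len(nrow(meta)), function(i) {
    rep_vec <- as.numeric(meta[i, paste0("pcss_", items)])
    names(rep_vec) <- items
    zemek_features(meta[i, ], rep_vec)
  }, numeric(9)))
}

#' Run the PPCS prognosis experiment end to end
#'
#' Simulates (or accepts) a cohort and count matrix, preprocesses,
#' labels, splits the initial-window samples into training / evaluation
#' / testing sets, selects features on the training set only, trains the
#' radial-SVM ncRNA model, tunes the probability threshold on the
#' evaluation set, evaluates on the naive testing set, and compares the
#' ncRNA model with a modified Zemek-score model and a combined model by
#' repeated cross-validation with DeLong inference.
#'
#' @param config a [run_config()].
#' @param cohort,counts optional pre-built inputs (simulated when NULL).
#' @return a `prognosis_report` list; see the examples in the package
#'   vignette.
#' @export
run_prognosis_experiment <- function(config = run_config(),
                                     cohort = NULL, counts = NULL) {
  st <- stage_inputs(config, cohort, counts)
  meta <- st$meta
  init <- meta[meta$days_post_injury <= config$sim$initial_window_days, ]
  split <- split_samples(init, config$split_fractions, seed = config$seed)
  init$set <- split$set[match(init$sample_id, split$sample_id)]

  Xall <- sample_feature_matrix(st$pre, init)
  rna_features <- setdiff(colnames(Xall), "age")
  tr <- init$set == "training"
  ev <- init$set == "evaluation"
  te <- init$set == "testing"
  y <- init$label

  if (config$run_selection) {
    tr_counts <- subset_ncrna_samples(st$pre$counts, init$sample_id[tr])
    sel <- select_features(
      Xall[tr, rna_features, drop = FALSE], y[tr], counts = tr_counts,
      numeric_responses = list(pcss_total = init$pcss_total[tr],
                               days_post_injury = init$days_post_injury[tr]),
      binary_responses = list(ppcs = y[tr]),
      cfg = config$selection, seed = config$seed)
    panel <- sel$panel$feature_id
  } else {
    sel <- NULL
    panel <- rna_features
  }
  model_feats <- c(panel, "age")  # age always joins the final model

  rna_model <- train_classifier(Xall[tr, model_feats, drop = FALSE],
                                y[tr], "rsvm", config$svm_hyperparams,
                                seed = config$seed)
  probs_ev <- predict_prob(rna_model, Xall[ev, model_feats, drop = FALSE])
  thr_opt <- optimize_threshold(probs_ev, y[ev],
                                config$threshold_objective)
  probs_te <- predict_prob(rna_model, Xall[te, model_feats, drop = FALSE])
  probs_tr <- predict_prob(rna_model, Xall[tr, model_feats, drop = FALSE])

  metrics <- list(
    training = confusion_metrics(probs_tr, y[tr], thr_opt),
    evaluation = confusion_metrics(probs_ev, y[ev], thr_opt),
    testing = confusion_metrics(probs_te, y[te], thr_opt))
  testing_roc <- delong_ci(probs_te, y[te])

  # clinical comparator and combined model, compared by repeated CV on
  # the training samples
  Z <- zemek_feature_matrix(init)
  rownames(Z) <- init$sample_id
  cv_rna <- repeated_cv(Xall[tr, model_feats, drop = FALSE], y[tr],
                        "rsvm", config$cv_k, config$cv_reps,
                        seed = config$seed,
                        hyperparams = config$svm_hyperparams)
  cv_zemek <- repeated_cv(cbind(Z, age = init$age)[tr, , drop = FALSE],
                          y[tr], "rsvm", config$cv_k, config$cv_reps,
                          seed = config$seed,
                          hyperparams = config$svm_hyperparams)
  cv_comb <- repeated_cv(cbind(Xall[, model_feats, drop = FALSE], Z)[tr, ,
                                                                     drop = FALSE],
                         y[tr], "rsvm", config$cv_k, config$cv_reps,
                         seed = config$seed,
                         hyperparams = config$svm_hyperparams)
  cmp <- list(
    rna_vs_zemek = delong_test(cv_rna$probs, cv_zemek$probs, y[tr]),
    combined_vs_rna = delong_test(cv_comb$probs, cv_rna$probs, y[tr]))

  structure(list(
    threshold = st$threshold, labels = st$labels, split = split,
    set_sizes = table(init$set), set_tallies = attr(split, "tallies"),
    panel = panel, selection = sel, model = rna_model,
    probability_threshold = thr_opt, metrics = metrics,
    testing_roc = testing_roc,
    cv = list(rna = cv_rna, zemek = cv_zemek, combined = cv_comb),
    comparisons = cmp, seed = config$seed),
    class = "prognosis_report")
}

#' @export
print.prognosis_report <- function(x, ...) {
  cat("PPCS prognosis experiment (seed", x$seed, ")\n")
  cat("  panel:", length(x$panel), "ncRNA features + age\n")
  cat(sprintf("  probability threshold (evaluation-tuned): %.2f\n",
              as.numeric(x$probability_threshold)))
  cat(sprintf("  testing AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$testing_roc$auc, x$testing_roc$ci_low,
              x$testing_roc$ci_high))
  cat(sprintf("  CV AUC: RNA %.3f | Zemek %.3f | RNA+Zemek %.3f\n",
              x$cv$rna$auc, x$cv$zemek$auc, x$cv$combined$auc))
  invisible(x)
}

subset_ncrna_samples <- function(m, sample_ids) {
  seqs <- m$features$sequence
  names(seqs) <- m$features$feature_id
  ncrna_counts(m$counts[, sample_ids, drop = FALSE],
               m$features$category, seqs[!is.na(seqs)])
}

#' Run the recovery-detection experiment end to end
#'
#' On follow-up samples (>= 21 days post-injury, one labeling sample per
#' participant, samples within `near_threshold_margin` PCSS points of
#' the threshold excluded), compares three random-forest models of
#' recovery status by repeated cross-validation: balance + cognition +
#' age, ncRNA + age, and the combination; reports AUCs with DeLong CIs
#' and pairwise DeLong tests.
#'
#' @param config a [run_config()].
#' @param cohort,counts optional pre-built inputs.
#' @param rna_panel optional character vector of ncRNA features for the
#'   RNA model; when NULL the selection pipeline runs on the follow-up
#'   samples.
#' @return a `recovery_report` list.
#' @export
run_recovery_experiment <- function(config = run_config(),
                                    cohort = NULL, counts = NULL,
                                    rna_panel = NULL) {
  st <- stage_inputs(config, cohort, counts)
  meta <- st$meta
  lab <- st$labels$labels
  fu <- meta[meta$sample_id %in% lab$labeling_sample_id, ]
  n_before <- nrow(fu)
  fu <- filter_near_threshold(fu, st$threshold,
                              config$near_threshold_margin)
  n_excluded <- attr(fu, "n_removed")

  ft <- config$sim$functional_tests$test
  balcog <- as.matrix(cbind(fu[, ft], age = fu$age))
  rownames(balcog) <- fu$sample_id
  X <- sample_feature_matrix(st$pre, fu)
  y <- droplevels(fu$label)

  if (is.null(rna_panel)) {
    if (config$run_selection) {
      sel <- select_features(
        X[, setdiff(colnames(X), "age"), drop = FALSE], y,
        counts = subset_ncrna_samples(st$pre$counts, fu$sample_id),
        numeric_responses = list(pcss_total = fu$pcss_total),
        cfg = config$selection, seed = config$seed)
      rna_panel <- sel$panel$feature_id
    } else {
      rna_panel <- setdiff(colnames(X), "age")
    }
  }
  rna <- X[, c(rna_panel, "age"), drop = FALSE]

  cv_bc <- repeated_cv(balcog, y, "random_forest", config$cv_k,
                       config$cv_reps, seed = config$seed)
  cv_rna <- repeated_cv(rna, y, "random_forest", config$cv_k,
                        config$cv_reps, seed = config$seed)
  cv_comb <- repeated_cv(cbind(balcog, rna[, rna_panel, drop = FALSE]),
                         y, "random_forest", config$cv_k,
                         config$cv_reps, seed = config$seed)
  cmp <- list(
    rna_vs_balcog = delong_test(cv_rna$probs, cv_bc$probs, y),
    combined_vs_balcog = delong_test(cv_comb$probs, cv_bc$probs, y),
    combined_vs_rna = delong_test(cv_comb$probs, cv_rna$probs, y))

  structure(list(threshold = st$threshold, n_samples = nrow(fu),
                 n_excluded_near_threshold = n_excluded,
                 n_candidates = n_before,
                 rna_panel = rna_panel,
                 cv = list(balcog = cv_bc, rna = cv_rna,
                           combined = cv_comb),
                 comparisons = cmp, seed = config$seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("mTBI recovery experiment (seed", x$seed, ")\n")
  cat("  follow-up samples:", x$n_samples,
      sprintf("(%d excluded near threshold)\n",
              x$n_excluded_near_threshold))
  cat(sprintf("  CV AUC: BalCog %.3f | RNA %.3f | combined %.3f\n",
              x$cv$balcog$auc, x$cv$rna$auc, x$cv$combined$auc))
  invisible(x)
}

#' Write an experiment report as JSON
#'
#' Serializes the headline metrics (AUCs, CIs, threshold, confusion
#' metrics, panel, seed) of a prognosis or recovery report.
#'
#' @param report a `prognosis_report` or `recovery_report`.
#' @param path file path.
#' @export
write_report_json <- function(report, path) {
  out <- if (inherits(report, "prognosis_report")) {
    list(kind = "prognosis", seed = report$seed,
         panel = report$panel,
         probability_threshold = as.numeric(report$probability_threshold),
         testing = report$testing_roc, metrics = report$metrics,
         cv_auc = lapply(report$cv, function(r)
           list(auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high)),
         comparisons = report$comparisons)
  } else {
    list(kind = "recovery", seed = report$seed,
         rna_panel = report$rna_panel,
         n_excluded_near_threshold = report$n_excluded_near_threshold,
         cv_auc = lapply(report$cv, function(r)
           list(auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high)),
         comparisons = report$comparisons)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
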