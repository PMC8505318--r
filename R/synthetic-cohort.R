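#' Simulation configuration for a synthetic mTBI cohort
#'
#' Defaults reproduce the design of the study cohort the downstream
#' analysis assumes: 112 participants aged 8-24, 28.6% with persistent
#' post-concussion symptoms (PPCS), each contributing an initial saliva
#' sample within 14 days of injury and at least one follow-up sample from
#' 21 days onward (about 4.5 samples per participant, ~505 in total),
#' 22-item PCSS symptom reports (each item 0-6), eight balance and four
#' cognitive test scores with test-retest noise, and a negative-binomial
#' small-RNA count matrix over three categories with planted group and
#' day-post-injury effects.
#'
#' @param n_participants number of injured participants.
#' @param ppcs_prevalence designed proportion of PPCS participants.
#' @param age_range integer pair, inclusive age bounds in years.
#' @param samples_per_participant integer pair: min/max samples per
#'   participant (at least 3: two initial-window samples and one
#'   follow-up).
#' @param initial_window_days latest day post-injury counted as an
#'   "initial" sample.
#' @param followup_min_days earliest day post-injury counted as a
#'   "follow-up" (PPCS-labeling) sample.
#' @param max_day last day of observation post-injury.
#' @param n_features_per_category named integer vector with entries
#'   `miRNA`, `snoRNA`, `piRNA`.
#' @param nb_size negative-binomial size (dispersion) parameter shared by
#'   all features; variance = mu + mu^2/size.
#' @param library_size expected per-sample total read count after
#'   alignment and category assignment.
#' @param library_size_cv coefficient of variation of per-sample library
#'   sizes on the log scale (0 fixes every library at `library_size`).
#' @param planted_effects list of [effect_spec()] entries; the default
#'   plants 16 PPCS group effects (7 miRNA, 1 snoRNA, 8 piRNA,
#'   |log2FC| = 1.5) and 12 miRNA day-post-injury trends.
#' @param exact_allocation logical; when TRUE (default) exactly
#'   `round(n * prevalence)` participants are PPCS-designated (stable for
#'   small cohorts); when FALSE the designation is binomial.
#' @param control_mean,control_sd,control_n summary of the non-injured
#'   control PCSS distribution used to derive the PPCS threshold; the
#'   paper-era values (mean 3.5, sd 4, n 170) give threshold 5.
#' @param baseline_severity named vector `mean`/`sd` of the expected
#'   initial PCSS total.
#' @param ppcs_baseline_shift added to the expected initial PCSS total of
#'   PPCS-designated participants (initial symptom burden is higher in
#'   the PPCS group).
#' @param tau_nonppcs,tau_ppcs named vectors `mean`/`sd` of the
#'   exponential symptom decay time constant (days); PPCS participants
#'   decay much more slowly.
#' @param functional_tests data.frame describing the 12 functional tests;
#'   see [default_functional_tests()].
#' @param include_sequences logical; when TRUE piRNA features carry
#'   random 26-31 nt sequences, with some near-identical families so the
#'   wiRNA clustering stage has work to do.
#' @param seed integer seed controlling every random draw.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_participants = 112L,
                       ppcs_prevalence = 32 / 112,
                       age_range = c(8L, 24L),
                       samples_per_participant = c(3L, 6L),
                       initial_window_days = 14L,
                       followup_min_days = 21L,
                       max_day = 60L,
                       n_features_per_category =
                         c(miRNA = 150L, snoRNA = 50L, piRNA = 100L),
                       nb_size = 5,
                       library_size = 1e5,
                       library_size_cv = 0.2,
                       planted_effects = NULL,
                       exact_allocation = TRUE,
                       control_mean = 3.5, control_sd = 4, control_n = 170L,
                       baseline_severity = c(mean = 40, sd = 12),
                       ppcs_baseline_shift = 15,
                       tau_nonppcs = c(mean = 7, sd = 1.5),
                       tau_ppcs = c(mean = 45, sd = 10),
                       functional_tests = default_functional_tests(),
                       include_sequences = TRUE,
                       seed = 1L) {
  if (n_participants < 1) stop_bad_arg("n_participants must be positive")
  if (ppcs_prevalence <= 0 || ppcs_prevalence >= 1)
    stop_bad_arg("ppcs_prevalence must be in (0,1)")
  if (initial_window_days >= followup_min_days)
    stop_bad_arg("initial_window_days must be < followup_min_days")
  if (any(n_features_per_category < 1) ||
      !all(c("miRNA", "snoRNA", "piRNA") %in%
           names(n_features_per_category)))
    stop_bad_arg("n_features_per_category needs positive miRNA/snoRNA/piRNA")
  if (nb_size <= 0) stop_bad_arg("nb_size must be positive")
  if (samples_per_participant[1] < 3)
    stop_bad_arg("need at least 3 samples per participant")
  cfg <- list(
    n_participants = as.integer(n_participants),
    ppcs_prevalence = ppcs_prevalence,
    age_range = as.integer(age_range),
    samples_per_participant = as.integer(samples_per_participant),
    initial_window_days = as.integer(initial_window_days),
    followup_min_days = as.integer(followup_min_days),
    max_day = as.integer(max_day),
    n_features_per_category = n_features_per_category,
    nb_size = nb_size,
    library_size = library_size,
    library_size_cv = library_size_cv,
    planted_effects = planted_effects %||%
      default_planted_effects(n_features_per_category),
    exact_allocation = isTRUE(exact_allocation),
    control_mean = control_mean, control_sd = control_sd,
    control_n = as.integer(control_n),
    baseline_severity = baseline_severity,
    ppcs_baseline_shift = ppcs_baseline_shift,
    tau_nonppcs = tau_nonppcs, tau_ppcs = tau_ppcs,
    functional_tests = functional_tests,
    include_sequences = isTRUE(include_sequences),
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Planted simulation effect on one feature
#'
#' @param feature_id feature affected.
#' @param covariate one of `ppcs_status` (group fold change),
#'   `days_post_injury` (per-day log2 slope), `symptom_item` (log2 fold
#'   change scaled by an item score / 6).
#' @param log2fc log2 fold change (for `ppcs_status`/`symptom_item`) or
#'   per-day log2 slope (for `days_post_injury`).
#' @param item symptom item name, required for `symptom_item`.
#' @export
effect_spec <- function(feature_id,
                        covariate = c("ppcs_status", "days_post_injury",
                                      "symptom_item"),
                        log2fc, item = NULL) {
  covariate <- match.arg(covariate)
  if (covariate == "symptom_item" && is.null(item))
    stop_bad_arg("symptom_item effects need an item name")
  structure(list(feature_id = feature_id, covariate = covariate,
                 log2fc = log2fc, item = item), class = "effect_spec")
}

#' Default planted effects
#'
#' 16 PPCS group-effect features mirroring the scale of the prognostic
#' panel (7 miRNA up/down at |log2FC| 1.5, 1 snoRNA, 8 piRNA -- the
#' piRNA effects echo the observation that most group differences
#' involved piRNA clusters), plus 12 miRNAs with a negative
#' day-post-injury trend (log2 slope -0.02/day), echoing the dominant
#' days-post-injury associations of the correlation scan.
#'
#' @param n_features_per_category as in [sim_config()].
#' @return list of [effect_spec()].
#' @export
default_planted_effects <- function(n_features_per_category =
                                      c(miRNA = 150L, snoRNA = 50L,
                                        piRNA = 100L)) {
  stopifnot(n_features_per_category["miRNA"] >= 31,
            n_features_per_category["snoRNA"] >= 1,
            n_features_per_category["piRNA"] >= 8)
  eff <- list()
  sgn <- rep(c(1, -1), length.out = 7)
  for (i in 1:7)
    eff <- c(eff, list(effect_spec(sprintf("miR-sim-%03d", i),
                                   "ppcs_status", sgn[i] * 1.5)))
  eff <- c(eff, list(effect_spec("SNORD-sim-001", "ppcs_status", 1.5)))
  for (i in 1:8)  # piRNA group effects mostly up in PPCS
    eff <- c(eff, list(effect_spec(sprintf("piR-sim-%03d", i),
                                   "ppcs_status",
                                   ifelse(i <= 6, 1.5, -1.5))))
  for (i in 20:31)
    eff <- c(eff, list(effect_spec(sprintf("miR-sim-%03d", i),
                                   "days_post_injury", -0.02)))
  eff
}

#' Feature ids of the planted PPCS group effects
#'
#' Convenience accessor used by recovery benchmarks.
#' @param config a [sim_config()].
#' @return character vector of planted group-effect feature ids.
#' @export
planted_group_features <- function(config) {
  ids <- vapply(config$planted_effects, function(e)
    if (e$covariate == "ppcs_status") e$feature_id else NA_character_,
    character(1))
  ids[!is.na(ids)]
}

#' Default functional test battery
#'
#' Eight body-sway stances (sway index; lower = better) and four
#' reaction-time based cognitive tests (milliseconds; lower = better).
#' `improvement` is the mean follow-up improvement of non-PPCS
#' participants; it exceeds the minimal detectable change
#' (1.96 * sqrt(2) * sd_between * sqrt(1 - icc)) for TLEO, TLEC and the
#' three reaction-time tests that separate the groups at follow-up
#' (SRT1, PRT, SRT2), and stays below it elsewhere. PPCS participants do
#' not improve in expectation.
#'
#' @return data.frame with columns `test`, `type`, `mean`, `sd_between`,
#'   `noise_sd`, `improvement`, `icc`.
#' @export
default_functional_tests <- function() {
  data.frame(
    test = c("TLEO", "TSEO", "TLEC", "TSEC", "TLEOFP", "TLECFP",
             "TSEOFP", "TSECFP", "SRT1", "PRT", "GNG", "SRT2"),
    type = rep(c("balance", "cognitive"), c(8, 4)),
    mean = c(0.4, 0.9, 0.6, 1.4, 0.6, 0.9, 1.5, 2.2,
             290, 650, 480, 300),
    sd_between = c(0.10, 0.22, 0.15, 0.35, 0.15, 0.22, 0.37, 0.55,
                   40, 70, 60, 40),
    noise_sd = c(0.04, 0.09, 0.06, 0.14, 0.06, 0.09, 0.15, 0.22,
                 12, 20, 18, 12),
    improvement = c(0.16, 0.05, 0.25, 0.1, 0.04, 0.06, 0.1, 0.15,
                    50, 90, 20, 55),
    icc = c(rep(0.85, 8), rep(0.9, 4)),
    stringsAsFactors = FALSE)
}

# Largest-remainder integer allocation of n into parts proportional to w.
largest_remainder <- function(n, w) {
  w <- w / sum(w)
  raw <- n * w
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Canonical PCSS item weights: headache carries the largest share of the
# expected total, followed by the common cognitive items; remaining mass
# is spread over the other items. Weights sum to 1.
pcss_item_weights <- function() {
  items <- pcss_items()$item
  w <- rep(1, length(items))
  names(w) <- items
  w["headache"] <- 3
  w["difficulty_concentrating"] <- 2.2
  w["fatigue"] <- 2
  w["dizziness"] <- 1.8
  w["sensitivity_to_light"] <- 1.5
  w["sensitivity_to_noise"] <- 1.5
  w["feeling_slowed_down"] <- 1.5
  w / sum(w)
}

#' Generate a synthetic longitudinal mTBI cohort
#'
#' Draws participants (demographics, medical history, injury
#' characteristics, latent PPCS designation) and their longitudinal
#' samples with 22-item PCSS symptom reports. The expected PCSS total
#' decays exponentially, `baseline * exp(-days / tau)`, with the decay
#' time constant `tau` drawn much larger for PPCS-designated
#' participants, so symptom burden persists past the follow-up window
#' for them and resolves for the rest. Item scores are binomial(6) draws
#' around category-weighted shares of the expected total.
#'
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return an `mtbi_cohort` list with data.frames `participants` and
#'   `samples`, plus the `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_participants
  withr::with_seed(config$seed, {
    pid <- sprintf("P%03d", seq_len(n))
    n_ppcs <- if (config$exact_allocation)
      round(n * config$ppcs_prevalence)
    else rbinom(1, n, config$ppcs_prevalence)
    ppcs <- rep(FALSE, n)
    ppcs[sample(n, n_ppcs)] <- TRUE

    age <- sample(seq(config$age_range[1], config$age_range[2]), n,
                  replace = TRUE)
    sex <- rep("M", n)
    sex[sample(n, round(0.44 * n))] <- "F"

    # Prior concussions: exact allocation of the 27/112 with >= 1 prior,
    # split 16:8:3 across 1/2/3 priors.
    n_prior <- largest_remainder(round(n * 27 / 112), c(16, 8, 3))
    prior <- rep(0L, n)
    who <- sample(n, sum(n_prior))
    prior[who] <- rep(1:3, times = n_prior)
    prior_dur <- rep(NA_real_, n)
    prior_dur[prior > 0] <- round(rlnorm(sum(prior > 0),
                                         meanlog = log(6), sdlog = 0.8))

    chronic_headaches <- runif(n) < ifelse(ppcs, 7 / 32, 3 / 80)
    migraine_history <- runif(n) < 0.09
    sports_cause <- runif(n) < ifelse(ppcs, 18 / 32, 64 / 80)
    loss_of_consciousness <- runif(n) < ifelse(ppcs, 10 / 32, 12 / 80)

    baseline <- rnorm(n, config$baseline_severity["mean"],
                      config$baseline_severity["sd"]) +
      ifelse(ppcs, config$ppcs_baseline_shift, 0)
    baseline <- pmax(baseline, 8)
    tau <- ifelse(ppcs,
                  rnorm(n, config$tau_ppcs["mean"], config$tau_ppcs["sd"]),
                  rnorm(n, config$tau_nonppcs["mean"],
                        config$tau_nonppcs["sd"]))
    tau <- pmax(tau, 2)

    participants <- data.frame(
      participant_id = pid, age = age, sex = sex,
      chronic_headaches = chronic_headaches,
      migraine_history = migraine_history,
      prior_concussions = prior,
      prior_symptom_duration_days = prior_dur,
      sports_cause = sports_cause,
      loss_of_consciousness = loss_of_consciousness,
      ppcs_designated = ppcs,
      symptom_baseline = baseline, symptom_tau = tau,
      stringsAsFactors = FALSE)

    w <- pcss_item_weights()
    items <- names(w)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      k <- sample(seq(config$samples_per_participant[1],
                      config$samples_per_participant[2]), 1)
      # two guaranteed initial-window samples, one guaranteed follow-up
      days <- c(sample(1:7, 1),
                sample(8:config$initial_window_days, 1),
                sample(config$followup_min_days:
                         min(config$followup_min_days + 14, config$max_day),
                       1))
      if (k > 3)
        days <- c(days, sample(3:config$max_day, k - 3, replace = TRUE))
      days <- sort(unique(days))
      expected <- baseline[i] * exp(-days / tau[i])
      pcss <- t(vapply(expected, function(e) {
        p <- pmin(pmax(e * w / 6, 0), 1)
        rbinom(length(items), 6L, p)
      }, integer(length(items))))
      colnames(pcss) <- paste0("pcss_", items)
      rows[[i]] <- data.frame(
        sample_id = sprintf("%s_S%02d", pid[i], seq_along(days)),
        participant_id = pid[i], days_post_injury = days,
        pcss_total = rowSums(pcss), pcss,
        stringsAsFactors = FALSE)
    }
    samples <- do.call(rbind, rows)
    rownames(samples) <- NULL
  })
  structure(list(participants = participants, samples = samples,
                 config = config),
            class = "mtbi_cohort")
}

#' @export
print.mtbi_cohort <- function(x, ...) {
  cat("mtbi_cohort:", nrow(x$participants), "participants,",
      nrow(x$samples), "samples\n")
  cat("PPCS-designated:", sum(x$participants$ppcs_designated), "\n")
  invisible(x)
}

#' Simulate non-injured control PCSS totals
#'
#' Draws the control symptom distribution (negative binomial with the
#' configured mean; size 1.3 gives an sd close to the configured one)
#' used to derive the PPCS threshold. Deterministic given the config
#' seed.
#'
#' @param config a [sim_config()].
#' @return integer vector of `control_n` PCSS totals.
#' @export
simulate_control_scores <- function(config = sim_config()) {
  withr::with_seed(config$seed + 17L, {
    rnbinom(config$control_n, size = 1.3, mu = config$control_mean)
  })
}

#' Fill in balance and cognitive test scores
#'
#' Initial scores are drawn from a distribution shared by both groups
#' (no group effect before recovery diverges); from the follow-up window
#' onward, non-PPCS participants improve by each test's configured mean
#' improvement while PPCS participants stay static in expectation.
#' Test-retest noise has the configured per-test sd. Lower = better for
#' all 12 tests.
#'
#' @param cohort an `mtbi_cohort`.
#' @param config a [sim_config()]; defaults to the cohort's own config.
#' @return the cohort with one column per test added to `samples`.
#' @export
simulate_functional_scores <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "mtbi_cohort"))
  ft <- config$functional_tests
  s <- cohort$samples
  p <- cohort$participants
  ppcs <- p$ppcs_designated[match(s$participant_id, p$participant_id)]
  late <- s$days_post_injury >= config$followup_min_days
  withr::with_seed(config$seed + 1L, {
    for (j in seq_len(nrow(ft))) {
      base <- rnorm(nrow(p), ft$mean[j], ft$sd_between[j])
      bi <- base[match(s$participant_id, p$participant_id)]
      drop <- ifelse(late & !ppcs, ft$improvement[j], 0)
      noise <- if (ft$noise_sd[j] > 0)
        rnorm(nrow(s), 0, ft$noise_sd[j]) else 0
      s[[ft$test[j]]] <- bi - drop + noise
    }
  })
  cohort$samples <- s
  cohort
}

# Random piRNA-like sequences with near-identical families: every third
# sequence is a 1-2 mismatch variant of its predecessor, so single-linkage
# clustering at 0.9 identity finds non-trivial wiRNA clusters.
random_pirna_sequences <- function(ids) {
  n <- length(ids)
  seqs <- character(n)
  for (i in seq_len(n)) {
    if (i > 1 && i %% 3 == 0) {
      s <- strsplit(seqs[i - 1], "")[[1]]
      pos <- sample(length(s), sample(1:2, 1))
      s[pos] <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
      seqs[i] <- paste(s, collapse = "")
    } else {
      len <- sample(26:31, 1)
      seqs[i] <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                       collapse = "")
    }
  }
  names(seqs) <- ids
  seqs
}

#' Simulate a small-RNA count matrix for a cohort
#'
#' Per-feature baseline relative abundances are log-normal; expected
#' counts are `library_size * abundance * planted multipliers`, and
#' observed counts are negative binomial with the configured shared size
#' parameter. Planted group effects multiply the mean by `2^log2fc` for
#' samples of PPCS-designated participants; day effects by
#' `2^(slope * days)`; symptom-item effects by `2^(log2fc * item/6)`.
#' Per-sample library sizes vary log-normally (sd 0.2 on the log scale).
#' Deterministic given the config seed.
#'
#' @param cohort an `mtbi_cohort`.
#' @param config a [sim_config()]; defaults to the cohort's own config.
#' @return an [ncrna_counts()] with one column per cohort sample.
#' @export
simulate_counts <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "mtbi_cohort"))
  if (nrow(cohort$samples) == 0) stop_bad_arg("cohort has no samples")
  nfc <- config$n_features_per_category
  ids <- c(sprintf("miR-sim-%03d", seq_len(nfc["miRNA"])),
           sprintf("SNORD-sim-%03d", seq_len(nfc["snoRNA"])),
           sprintf("piR-sim-%03d", seq_len(nfc["piRNA"])))
  cats <- rep(c("miRNA", "snoRNA", "piRNA"), nfc)
  for (e in config$planted_effects)
    if (!e$feature_id %in% ids)
      stop_bad_arg("planted effect references unknown feature: ",
                   e$feature_id)
  s <- cohort$samples
  p <- cohort$participants
  ppcs <- p$ppcs_designated[match(s$participant_id, p$participant_id)]
  withr::with_seed(config$seed + 2L, {
    abund <- rlnorm(length(ids), meanlog = log(100), sdlog = 1.2)
    abund <- abund / sum(abund)
    libsize <- config$library_size *
      rlnorm(nrow(s), 0, config$library_size_cv)
    logmult <- matrix(0, length(ids), nrow(s),
                      dimnames = list(ids, s$sample_id))
    for (e in config$planted_effects) {
      if (e$covariate == "ppcs_status")
        logmult[e$feature_id, ] <- logmult[e$feature_id, ] +
          e$log2fc * as.numeric(ppcs)
      else if (e$covariate == "days_post_injury")
        logmult[e$feature_id, ] <- logmult[e$feature_id, ] +
          e$log2fc * s$days_post_injury
      else
        logmult[e$feature_id, ] <- logmult[e$feature_id, ] +
          e$log2fc * s[[paste0("pcss_", e$item)]] / 6
    }
    mu <- outer(abund, libsize) * 2^logmult
    counts <- matrix(rnbinom(length(mu), size = config$nb_size, mu = mu),
                     nrow(mu), ncol(mu), dimnames = dimnames(logmult))
    seqs <- if (config$include_sequences)
      random_pirna_sequences(ids[cats == "piRNA"]) else NULL
  })
  ncrna_counts(counts, cats, seqs)
}
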