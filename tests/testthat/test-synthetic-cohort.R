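test_that("cohort generation is deterministic and honours design constraints", {
  cfg <- tiny_config(seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_identical(simulate_counts(a)$counts, simulate_counts(b)$counts)
  expect_identical(simulate_functional_scores(a)$samples,
                   simulate_functional_scores(b)$samples)

  p <- a$participants
  expect_true(all(p$age >= 8 & p$age <= 24))
  s <- a$samples
  by_pt <- split(s$days_post_injury, s$participant_id)
  expect_true(all(vapply(by_pt, function(d) any(d <= 14), logical(1))))
  expect_true(all(vapply(by_pt, function(d) any(d >= 21), logical(1))))
  items <- as.matrix(s[, paste0("pcss_", pcss_items()$item)])
  expect_true(all(items >= 0 & items <= 6))
  expect_equal(unname(rowSums(items)), s$pcss_total)
})

test_that("PPCS designation matches the configured prevalence", {
  # exact allocation at the study scale: 112 x 28.6% -> 32
  co <- generate_cohort(sim_config(seed = 5))
  expect_equal(sum(co$participants$ppcs_designated), 32)
  # binomial mode stays within binomial 99% bounds of the prevalence
  hits <- vapply(1:30, function(s) {
    co <- generate_cohort(tiny_config(seed = s, exact_allocation = FALSE))
    sum(co$participants$ppcs_designated)
  }, numeric(1))
  pr <- mean(hits) / 24
  se <- sqrt(0.286 * 0.714 / (24 * 30))
  expect_lt(abs(pr - 32 / 112), 2.58 * se + 1e-9)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(ppcs_prevalence = 1.2), "prevalence")
  expect_error(sim_config(initial_window_days = 25), "followup")
  expect_error(sim_config(nb_size = -1), "nb_size")
  cfg <- tiny_config(planted = list(effect_spec("no-such-feature",
                                                "ppcs_status", 1)))
  expect_error(simulate_counts(generate_cohort(cfg)), "unknown feature")
})

test_that("PPCS-designated participants decay more slowly and label accordingly", {
  co <- generate_cohort(sim_config(seed = 2))
  lab <- assign_ppcs(co$samples, 5)$labels
  des <- co$participants$ppcs_designated[
    match(lab$participant_id, co$participants$participant_id)]
  agreement <- mean((lab$label == "PPCS") == des)
  expect_gt(agreement, 0.9)
})

test_that("planted group fold changes appear in the sample means", {
  # log2FC = 2 feature: PPCS / non-PPCS mean count ratio near 4
  ratios <- vapply(1:3, function(s) {
    cfg <- sim_config(n_participants = 100L, ppcs_prevalence = 0.5,
                      n_features_per_category =
                        c(miRNA = 40L, snoRNA = 10L, piRNA = 12L),
                      planted_effects = list(
                        effect_spec("miR-sim-010", "ppcs_status", 2)),
                      seed = s)
    co <- generate_cohort(cfg)
    m <- simulate_counts(co)
    pid <- sub("_S.*", "", colnames(m$counts))
    ppcs <- co$participants$ppcs_designated[
      match(pid, co$participants$participant_id)]
    mean(m$counts["miR-sim-010", ppcs]) /
      mean(m$counts["miR-sim-010", !ppcs])
  }, numeric(1))
  expect_true(all(abs(ratios - 4) / 4 < 0.2))
})

test_that("counts approach the Poisson limit as the NB size grows", {
  cfg <- tiny_config(seed = 3, nb_size = 1e8, library_size_cv = 0)
  m <- simulate_counts(generate_cohort(cfg))
  mu <- rowMeans(m$counts)
  vmr <- apply(m$counts, 1, var) / mu
  keep <- mu > 20
  expect_lt(abs(median(vmr[keep]) - 1), 0.15)
  # and clearly overdispersed at the default size
  m2 <- simulate_counts(generate_cohort(tiny_config(seed = 3, nb_size = 0.5,
                                                    library_size_cv = 0)))
  vmr2 <- apply(m2$counts, 1, var) / rowMeans(m2$counts)
  expect_gt(median(vmr2[keep]), 3)
})

test_that("functional scores share an initial distribution and diverge at follow-up", {
  cfg <- sim_config(seed = 6)
  co <- simulate_functional_scores(generate_cohort(cfg))
  s <- merge(co$samples,
             co$participants[, c("participant_id", "ppcs_designated")],
             by = "participant_id")
  ft <- cfg$functional_tests
  init <- s[s$days_post_injury <= 14, ]
  late <- s[s$days_post_injury >= 21, ]
  for (tn in c("SRT1", "PRT", "SRT2")) {
    row <- ft[ft$test == tn, ]
    # no planted initial group effect: difference well below between-SD
    d0 <- abs(mean(init[[tn]][init$ppcs_designated]) -
                mean(init[[tn]][!init$ppcs_designated]))
    expect_lt(d0, row$sd_between)
    # non-PPCS mean improvement exceeds the test's MDC95
    imp <- mean(init[[tn]][!init$ppcs_designated]) -
      mean(late[[tn]][!late$ppcs_designated])
    mdc <- compute_mdc(row$sd_between, row$icc)$mdc95
    expect_gt(imp, mdc)
  }
})

test_that("zero noise and zero improvement make follow-up equal initial", {
  ft <- default_functional_tests()
  ft$noise_sd <- 0
  ft$improvement <- 0
  co <- simulate_functional_scores(
    generate_cohort(tiny_config(seed = 9, functional_tests = ft)))
  by_pt <- split(co$samples$SRT1, co$samples$participant_id)
  expect_true(all(vapply(by_pt, function(v) all(v == v[1]), logical(1))))
})

test_that("null features have equal group means at the nominal test rate", {
  # two-sample t on asinh-TSS values of a no-effect feature, many seeds
  rej <- vapply(1:200, function(s) {
    m <- null_count_matrix(p = 20, n = 24, seed = s)
    x <- asinh_transform(tss_normalize(m))
    grp <- balanced_labels(24)
    t.test(x[1, grp == "pos"], x[1, grp == "neg"])$p.value < 0.05
  }, logical(1))
  # binomial 99% bounds around 0.05 for 200 draws
  expect_lt(abs(mean(rej) - 0.05), 2.58 * sqrt(0.05 * 0.95 / 200))
})
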