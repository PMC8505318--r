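test_that("a perfectly separating feature survives multifold consensus", {
  set.seed(2)
  n <- 60
  y <- balanced_labels(n)
  X <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("f", 1:10)))
  X[, "f7"] <- ifelse(y == "pos", 2, -2) + rnorm(n, 0, 0.1)
  cfg <- selection_config(n_folds = 5, top_k_per_fold = 2,
                          learners = "random_forest")
  mf <- multifold_select(X, y, cfg, seed = 1)
  expect_true("f7" %in% mf$selected)
  expect_equal(mf$appearances[["f7"]], mf$n_lists)
  expect_error(multifold_select(X, y,
                                selection_config(top_k_per_fold = 99),
                                seed = 1), "top_k")
})

test_that("pure-noise inputs pass very few features through consensus", {
  # folds overlap, so features with chance correlations stay "important"
  # across folds; consensus bounds the spurious pass-through to a few
  # features out of a hundred rather than eliminating it
  counts <- vapply(1:5, function(s) {
    set.seed(s)
    X <- matrix(rnorm(60 * 100), 60,
                dimnames = list(NULL, paste0("f", 1:100)))
    y <- balanced_labels(60)
    cfg <- selection_config(n_folds = 5, top_k_per_fold = 5,
                            learners = "random_forest")
    length(multifold_select(X, y, cfg, seed = s)$selected)
  }, numeric(1))
  expect_lte(mean(counts), 5)   # at most the per-list budget
  expect_lt(mean(counts), 0.1 * 100)
})

test_that("the numeric GLM stream screens by unadjusted Pearson p", {
  set.seed(6)
  X <- matrix(rnorm(50 * 20), 50, dimnames = list(NULL, paste0("f", 1:20)))
  sel <- glm_stream_numeric(X, list(resp = X[, "f4"] + rnorm(50, 0, 0.1)))
  expect_true("f4" %in% sel)
  expect_length(glm_stream_numeric(X, list(resp = rnorm(50)), alpha = 0), 0)
  # null rate: about alpha * m selections per response
  hits <- vapply(1:5, function(s) {
    set.seed(100 + s)
    length(glm_stream_numeric(X, list(r = rnorm(50)), alpha = 0.05))
  }, numeric(1))
  expect_lt(mean(hits), 0.15 * 20)
  expect_warning(glm_stream_numeric(X, list(r = rep(2, 50))),
                 "zero variance")
})

test_that("the binary GLM stream contributes top features only past the kappa gate", {
  set.seed(8)
  n <- 80
  X <- matrix(rnorm(n * 12), n, dimnames = list(NULL, paste0("f", 1:12)))
  y <- factor(ifelse(X[, "f2"] > 0, "pos", "neg"), levels = c("neg", "pos"))
  sel <- glm_stream_binary(X, list(ppcs = y), seed = 1)
  expect_true("f2" %in% sel)
  expect_lte(length(attr(sel, "by_response")$ppcs), 3)

  # strict gate at exactly 0.20: no contribution
  gate_at <- function(k) {
    glm_stream_binary(X, list(ppcs = y), seed = 1,
                      .kappa_fun = function(...) k)
  }
  expect_length(gate_at(0.20), 0)
  expect_true(length(gate_at(0.21)) > 0)

  # response independent of X almost never passes
  passes <- vapply(1:5, function(s) {
    set.seed(200 + s)
    yr <- balanced_labels(n)[sample(n)]
    length(glm_stream_binary(X, list(r = yr), seed = s)) > 0
  }, logical(1))
  expect_lte(sum(passes), 1)
  expect_warning(glm_stream_binary(X, list(one = factor(rep("a", n)))),
                 "both classes")
})

test_that("stream union keeps provenance and rejects emptiness", {
  pan <- union_candidates(multifold = c("a", "b", "c"),
                          glm_numeric = c("d", "e"),
                          glm_binary = c("f", "g"))
  expect_equal(nrow(pan), 7)
  pan2 <- union_candidates(multifold = c("a", "b"),
                           glm_numeric = c("a", "b"))
  expect_equal(nrow(pan2), 2)
  expect_equal(pan2$provenance, rep("multifold,glm_numeric", 2))
  # a DE data.frame contributes its padj < 0.05 features
  de <- data.frame(feature_id = c("x", "y"), padj = c(0.01, 0.5))
  pan3 <- union_candidates(multifold = "a", de = de)
  expect_setequal(pan3$feature_id, c("a", "x"))
  expect_error(union_candidates(), "relax")
})

test_that("recursive feature elimination drops noise and returns a sub-panel", {
  set.seed(3)
  n <- 60
  y <- balanced_labels(n)
  X <- cbind(sig = ifelse(y == "pos", 1, 0) + rnorm(n, 0, 0.3),
             noise1 = rnorm(n), noise2 = rnorm(n))
  out <- rfe(X, y, colnames(X), selection_config(rfe_cv_folds = 5),
             seed = 1)
  expect_true("sig" %in% out$panel)
  expect_true(all(out$panel %in% colnames(X)))
  expect_lte(nrow(out$trace), ncol(X) + 1)
  # removed features improve the score monotonically along the trace
  expect_true(all(diff(out$trace$score) > 0) || nrow(out$trace) == 1)
  # size-1 panel is returned unchanged
  one <- rfe(X, y, "sig", selection_config(rfe_cv_folds = 5), seed = 1)
  expect_equal(one$panel, "sig")
  expect_error(rfe(X, y, character(0)), "empty")
  expect_error(rfe(X, y, "absent"), "absent")
})

test_that("GBM ranking orders a planted feature first", {
  set.seed(5)
  n <- 120
  y <- balanced_labels(n)
  X <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("f", 1:6)))
  X[, "f3"] <- ifelse(y == "pos", 1.5, -1.5) + rnorm(n, 0, 0.4)
  hits <- vapply(1:5, function(s)
    gbm_rank(X, y, colnames(X), seed = s)$feature_id[1] == "f3",
    logical(1))
  expect_gte(sum(hits), 4)
  rk <- gbm_rank(X, y, colnames(X), seed = 1)
  expect_setequal(rk$feature_id, colnames(X))
  expect_equal(rk$rank, 1:6)
  single <- gbm_rank(X, y, "f3", seed = 1)
  expect_equal(single$feature_id, "f3")
  expect_equal(single$rank, 1)
})

test_that("the full selection pipeline is deterministic given a seed", {
  set.seed(7)
  n <- 50
  y <- balanced_labels(n)
  X <- matrix(rnorm(n * 15), n, dimnames = list(NULL, paste0("f", 1:15)))
  X[, "f1"] <- ifelse(y == "pos", 1, -1) + rnorm(n, 0, 0.5)
  cfg <- selection_config(n_folds = 4, top_k_per_fold = 3,
                          learners = "random_forest", rfe_cv_folds = 4)
  a <- select_features(X, y, numeric_responses = list(r = X[, "f1"]),
                       cfg = cfg, seed = 9)
  b <- select_features(X, y, numeric_responses = list(r = X[, "f1"]),
                       cfg = cfg, seed = 9)
  expect_identical(a$panel, b$panel)
  expect_true("f1" %in% a$panel$feature_id)
})
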