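test_that("classifier training is seeded, probabilistic, and validated", {
  set.seed(1)
  n <- 60
  y <- balanced_labels(n)
  X <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("f", 1:4)))
  X[, 1] <- ifelse(y == "pos", 3, -3)
  for (kind in c("rsvm", "random_forest")) {
    fit <- train_classifier(X, y, kind, seed = 5)
    pr <- predict_prob(fit, X)
    expect_true(all(pr >= 0 & pr <= 1))
    expect_equal(auc_mann_whitney(pr, y), 1)  # separable toy data
    fit2 <- train_classifier(X, y, kind, seed = 5)
    expect_equal(predict_prob(fit2, X), pr)
  }
  expect_error(train_classifier(X, factor(rep("pos", n))), "single class")
})

test_that("repeated CV pools probabilities with a coherent DeLong CI", {
  set.seed(2)
  n <- 80
  y <- balanced_labels(n)
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("f", 1:3)))
  X[, 1] <- ifelse(y == "pos", 2, -2) + rnorm(n, 0, 0.3)
  cv <- repeated_cv(X, y, "rsvm", k = 5, reps = 3, seed = 4)
  expect_gte(cv$auc, 0.99)
  expect_lte(cv$ci_low, cv$auc)
  expect_gte(cv$ci_high, cv$auc)
  cv2 <- repeated_cv(X, y, "rsvm", k = 5, reps = 3, seed = 4)
  expect_identical(cv$probs, cv2$probs)
  expect_identical(cv$auc, cv2$auc)
  # minority class smaller than k triggers the fallback
  ys <- factor(c(rep("neg", 76), rep("pos", 4)), levels = c("neg", "pos"))
  expect_warning(cv3 <- repeated_cv(X, ys, "rsvm", k = 10, reps = 2,
                                    seed = 1), "k = 4")
  expect_equal(cv3$k, 4)
})

test_that("null labels give repeated-CV AUC intervals covering 0.5", {
  covered <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 120
    X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
    y <- balanced_labels(n)[sample(n)]
    cv <- repeated_cv(X, y, "rsvm", k = 5, reps = 2, seed = s)
    cv$ci_low <= 0.5 && cv$ci_high >= 0.5
  }, logical(1))
  expect_gte(sum(covered), 4)
})

test_that("threshold optimization maximizes the objective with the 0.5 tie rule", {
  y <- factor(rep(c("neg", "pos"), each = 5), levels = c("neg", "pos"))
  pr <- c(runif(5, 0, 0.3), runif(5, 0.7, 1))
  th <- optimize_threshold(pr, y)
  expect_equal(attr(th, "objective_value"), 1)
  expect_true(th > 0.3 && th < 0.7)
  # all-equal probabilities fall back to 0.5
  expect_equal(as.numeric(optimize_threshold(rep(0.4, 10), y)), 0.5)
  # imbalanced, calibrated probabilities push the cut below 0.5
  set.seed(9)
  n <- 300
  yi <- factor(rep(c("neg", "pos"), c(240, 60)), levels = c("neg", "pos"))
  pr2 <- plogis(ifelse(yi == "pos", 0.8, -1.6) + rnorm(n, 0, 0.8))
  expect_lt(as.numeric(optimize_threshold(pr2, yi)), 0.5)
  expect_error(optimize_threshold(pr, factor(rep("pos", 10))),
               "single class")
})

test_that("confusion metrics count the four cells correctly", {
  y <- factor(c("pos", "pos", "neg", "neg"), levels = c("neg", "pos"))
  cm <- confusion_metrics(c(0.9, 0.8, 0.3, 0.1), y, 0.5)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 1)
  expect_equal(cm$balanced_accuracy, 1)
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 4)
  cm0 <- confusion_metrics(c(0.9, 0.8, 0.3, 0.1), y, 0)
  expect_equal(cm0$sensitivity, 1)
  expect_equal(cm0$specificity, 0)
  perf <- confusion_metrics(c(1, 1, 0, 0), y, 0.5)
  expect_true(all(unlist(perf[c("sensitivity", "specificity", "ppv",
                                "npv", "balanced_accuracy")]) == 1))
})

test_that("the Mann-Whitney AUC handles ties and extremes", {
  lab <- factor(c("neg", "neg", "pos", "pos"), levels = c("neg", "pos"))
  expect_equal(auc_mann_whitney(c(0.2, 0.1, 0.9, 0.8), lab), 1)
  expect_equal(auc_mann_whitney(rep(0.5, 4), lab), 0.5)
  expect_error(auc_mann_whitney(1:3, factor(rep("a", 3))), "both classes")
  # invariance under strictly monotone transforms
  set.seed(3)
  sc <- rnorm(40); lb <- balanced_labels(40)
  a <- auc_mann_whitney(sc, lb)
  expect_equal(auc_mann_whitney(exp(sc), lb), a)
  expect_equal(auc_mann_whitney(rank(sc), lb), a)
})

test_that("DeLong inference matches pROC and degenerates sanely", {
  set.seed(7)
  n <- 150
  lb <- factor(rep(c("neg", "pos"), c(90, 60)), levels = c("neg", "pos"))
  latent <- rnorm(n) + (lb == "pos") * 1.2
  a <- latent + rnorm(n, 0, 0.7)
  b <- latent + rnorm(n, 0, 1.3)
  dt <- delong_test(a, b, lb)
  ci <- delong_ci(a, lb)
  skip_if_not_installed("pROC")
  ra <- pROC::roc(lb, a, quiet = TRUE)
  rb <- pROC::roc(lb, b, quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong")
  expect_equal(dt$z, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(dt$p_value, ref$p.value, tolerance = 1e-10)
  refci <- pROC::ci.auc(ra, method = "delong")
  expect_equal(ci$ci_low, refci[1], tolerance = 1e-10)
  expect_equal(ci$ci_high, refci[3], tolerance = 1e-10)
  # identical scores: zero difference, p = 1
  same <- delong_test(a, a, lb)
  expect_equal(same$auc_diff, 0)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  expect_error(delong_test(a, b[-1], lb), "paired")
})

test_that("DeLong CIs cover the true AUC at close to the nominal rate", {
  true_auc <- pnorm(1 / sqrt(2))  # binormal, unit separation
  covered <- vapply(1:200, function(s) {
    set.seed(s)
    lb <- factor(rep(c("neg", "pos"), each = 60), levels = c("neg", "pos"))
    sc <- rnorm(120) + (lb == "pos")
    ci <- delong_ci(sc, lb)
    ci$ci_low <= true_auc && ci$ci_high >= true_auc
  }, logical(1))
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.99)
})

test_that("Hanley-McNeil power reproduces the design calculations", {
  # training design: null 0.68 vs alternative 0.856, 53 pos / 131 neg
  expect_equal(round(100 * auc_power(0.68, 0.856, 53, 131)), 99)
  # testing design: alternative 0.87, 18 pos / 44 neg
  expect_lt(abs(100 * auc_power(0.68, 0.87, 18, 44) - 74), 1)
  # equal AUCs: power equals the significance level
  expect_equal(auc_power(0.68, 0.68, 53, 131), 0.05, tolerance = 1e-10)
  # strictly increasing in sample sizes and effect size
  expect_gt(auc_power(0.68, 0.856, 106, 131),
            auc_power(0.68, 0.856, 53, 131))
  expect_gt(auc_power(0.68, 0.856, 53, 262),
            auc_power(0.68, 0.856, 53, 131))
  expect_gt(auc_power(0.68, 0.9, 18, 44), auc_power(0.68, 0.87, 18, 44))
  expect_error(auc_power(0.4, 0.8, 10, 10), "0.5")
  expect_error(auc_power(0.68, 1, 10, 10), "0.5")
})

test_that("combining independent signal sources preserves performance", {
  wins <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 120
    y <- balanced_labels(n)
    A <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("a", 1:3)))
    B <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("b", 1:3)))
    A[, 1] <- A[, 1] + ifelse(y == "pos", 1.1, 0)
    B[, 1] <- B[, 1] + ifelse(y == "pos", 1.1, 0)
    cva <- repeated_cv(A, y, "rsvm", k = 5, reps = 2, seed = s)
    cvb <- repeated_cv(B, y, "rsvm", k = 5, reps = 2, seed = s)
    cvc <- repeated_cv(cbind(A, B), y, "rsvm", k = 5, reps = 2, seed = s)
    cvc$auc >= max(cva$auc, cvb$auc) - 0.05
  }, logical(1))
  expect_gte(sum(wins), 4)
})
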