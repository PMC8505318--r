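# Small in-code fixtures shared across test files.

# A compact cohort: 24 participants, no planted count effects unless
# requested, small feature space.
tiny_config <- function(seed = 1L, planted = list(), ...) {
  sim_config(n_participants = 24L, n_features_per_category =
               c(miRNA = 40L, snoRNA = 10L, piRNA = 12L),
             planted_effects = planted, seed = seed, ...)
}

# Random NB null count matrix (features x samples) with feature names.
null_count_matrix <- function(p = 60L, n = 30L, size = 5, seed = 1L) {
  withr::with_seed(seed, {
    mu <- rep(exp(rnorm(p, log(100), 1)), n)
    matrix(rnbinom(p * n, size = size, mu = mu), p, n,
           dimnames = list(sprintf("f%03d", 1:p), sprintf("s%03d", 1:n)))
  })
}

# Balanced two-class factor of length n (levels neg/pos).
balanced_labels <- function(n) {
  factor(rep(c("neg", "pos"), length.out = n), levels = c("neg", "pos"))
}

# A canonical zero PCSS report named by item.
zero_report <- function() setNames(rep(0, 22), pcss_items()$item)

# Brute-force BH step-up oracle: literal definition, quadratic loop.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  padj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) min(1, m * p[o][j] / j), numeric(1))
    padj_sorted[i] <- min(vals)
  }
  out <- numeric(m)
  out[o] <- padj_sorted
  out
}

# Pair-counting AUC oracle: double loop over positive x negative pairs
# with half credit for ties.
auc_oracle <- function(scores, labels, positive = levels(labels)[2]) {
  x <- scores[labels == positive]
  y <- scores[labels != positive]
  tot <- 0
  for (xi in x) for (yj in y)
    tot <- tot + (xi > yj) + 0.5 * (xi == yj)
  tot / (length(x) * length(y))
}
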