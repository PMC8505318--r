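#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up procedure: sort p ascending, compute `p_(i) * m / i`, enforce
#' monotonicity from the largest rank down, cap at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop_bad_arg("p-values must be in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / seq(m, 1)))[ro]
}

# Method-of-moments NB dispersion (alpha = 1/size) per feature, shrunk
# halfway toward the category median on the log scale would overweight
# tiny estimates; a simple arithmetic average with the category median is
# used instead. Counts are library-size-scaled before moments are taken;
# the Poisson component of the variance is removed via mean(1/s).
estimate_dispersions <- function(counts, size_factors, categories) {
  q <- sweep(counts, 2, size_factors, "/")
  m <- rowMeans(q)
  v <- apply(q, 1, var)
  alpha <- (v - m * mean(1 / size_factors)) / m^2
  alpha[!is.finite(alpha)] <- NA
  alpha <- pmax(alpha, 1e-8)
  med <- tapply(alpha, categories, median, na.rm = TRUE)
  med[is.na(med)] <- 0.1
  shrunk <- (alpha + med[categories]) / 2
  shrunk[is.na(shrunk)] <- med[categories][is.na(shrunk)]
  pmax(shrunk, 1e-8)
}

#' Negative-binomial Wald differential expression
#'
#' Per-feature NB generalized linear model with log link and per-sample
#' library-size offsets (log total counts). The dispersion is a
#' method-of-moments estimate shrunk toward the category median and held
#' fixed during the fit; the Wald statistic is the group coefficient
#' divided by its standard error (dispersion fixed at 1 in the
#' variance, as the NB family already carries the overdispersion).
#' Paired mode adds participant fixed effects, giving a within-person
#' initial-vs-follow-up contrast.
#'
#' Features with all-zero counts are flagged and returned with
#' `log2_fold_change = 0`, `p = 1`.
#'
#' @param m an [ncrna_counts()] or a counts matrix (features x samples);
#'   a matrix input needs a `categories` attribute or all features are
#'   treated as one category.
#' @param group factor of two levels over samples; the fold change is
#'   level 2 vs level 1.
#' @param paired optional factor of participant ids for paired designs.
#' @param fdr,fc cut-offs forwarded to [volcano_classify()].
#' @return data.frame `feature_id`, `category`, `base_mean`,
#'   `log2_fold_change`, `wald_z`, `p_value`, `padj`, `volcano_class`,
#'   `flag`.
#' @export
nb_wald_test <- function(m, group, paired = NULL, fdr = 0.05, fc = 1.5) {
  if (inherits(m, "ncrna_counts")) {
    counts <- m$counts
    categories <- m$features$category
  } else {
    counts <- as.matrix(m)
    categories <- attr(m, "categories") %||% rep("all", nrow(counts))
  }
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2)
    stop_bad_arg("group must have exactly 2 levels")
  if (min(table(group)) < 2)
    stop_bad_arg("need at least 2 samples per group")
  if (any(counts != round(counts)))
    stop_bad_arg("counts must be integers")
  lib <- colSums(counts)
  sf <- lib / mean(lib)
  alpha <- estimate_dispersions(counts, sf, categories)
  off <- log(lib)
  x <- if (is.null(paired)) model.matrix(~group)
    else model.matrix(~factor(paired) + group)
  gcol <- ncol(x)
  n <- nrow(counts)
  lfc <- z <- pv <- numeric(n)
  flag <- character(n)
  for (i in seq_len(n)) {
    y <- counts[i, ]
    if (all(y == 0)) {
      lfc[i] <- 0; z[i] <- 0; pv[i] <- 1; flag[i] <- "all_zero"
      next
    }
    fit <- tryCatch(
      suppressWarnings(glm.fit(x, y,
        family = MASS::negative.binomial(theta = 1 / alpha[i]),
        offset = off)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) flag[i] <- "no_convergence"
    if (is.null(fit)) { lfc[i] <- 0; z[i] <- 0; pv[i] <- 1; next }
    cf <- fit$coefficients[gcol]
    # Wald SE from the unscaled covariance (dispersion = 1)
    xw <- sqrt(fit$weights) * x
    cov <- tryCatch(chol2inv(chol(crossprod(xw))), error = function(e) NULL)
    if (is.null(cov) || is.na(cf)) {
      lfc[i] <- 0; z[i] <- 0; pv[i] <- 1
      flag[i] <- "singular_fit"
      next
    }
    se <- sqrt(cov[gcol, gcol])
    lfc[i] <- cf / log(2)
    z[i] <- cf / se
    pv[i] <- 2 * pnorm(-abs(z[i]))
  }
  padj <- bh_adjust(pv)
  data.frame(feature_id = rownames(counts), category = categories,
             base_mean = rowMeans(sweep(counts, 2, sf, "/")),
             log2_fold_change = lfc, wald_z = z, p_value = pv,
             padj = padj,
             volcano_class = volcano_classify(padj, lfc, fdr, fc),
             flag = flag, stringsAsFactors = FALSE)
}

#' Volcano-plot significance classes
#'
#' Four-way classification against an FDR cut-off and a linear-scale
#' fold-change cut-off: `both` (green; padj < fdr and |FC| > fc),
#' `fdr_only` (red), `fc_only` (yellow), `ns`.
#'
#' @param padj adjusted p-values.
#' @param log2fc log2 fold changes (|FC| > fc means |log2fc| > log2(fc)).
#' @param fdr,fc cut-offs (defaults 0.05 and 1.5).
#' @return factor with levels `ns`, `fdr_only`, `fc_only`, `both`.
#' @export
volcano_classify <- function(padj, log2fc, fdr = 0.05, fc = 1.5) {
  sig <- padj < fdr
  big <- abs(log2fc) > log2(fc)
  cls <- ifelse(sig & big, "both",
                ifelse(sig, "fdr_only", ifelse(big, "fc_only", "ns")))
  factor(cls, levels = c("ns", "fdr_only", "fc_only", "both"))
}

#' Pearson association scan of features against a response
#'
#' Per-feature Pearson correlation with `t = r * sqrt(n-2) /
#' sqrt(1-r^2)` and a two-sided p-value from the t distribution with
#' n - 2 df. `bh_threshold` is each feature's Benjamini-Hochberg step-up
#' significance cut-off, `rank * alpha / m`, at its p-value rank among
#' the unflagged features.
#'
#' @param X samples x features numeric matrix (normalized values).
#' @param y numeric response over samples (symptom item, functional
#'   score, or days post-injury).
#' @param alpha FDR level for the per-rank BH cut-offs (default 0.05).
#' @return data.frame `feature_id`, `r`, `t`, `p_value`, `bh_threshold`,
#'   `flagged` (zero-variance features are flagged and excluded from the
#'   BH ranking).
#' @export
pearson_scan <- function(X, y, alpha = 0.05) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop_bad_arg("need at least 3 samples")
  if (length(y) != n) stop_bad_arg("y must match the number of samples")
  if (sd(y) == 0) stop_bad_arg("response has zero variance")
  sds <- apply(X, 2, sd)
  flagged <- sds == 0
  r <- rep(NA_real_, ncol(X))
  r[!flagged] <- as.vector(cor(X[, !flagged, drop = FALSE], y))
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), n - 2)
  m <- sum(!flagged)
  bh <- rep(NA_real_, ncol(X))
  bh[!flagged] <- rank(p[!flagged], ties.method = "first") * alpha / m
  data.frame(feature_id = colnames(X) %||% as.character(seq_len(ncol(X))),
             r = r, t = tt, p_value = p, bh_threshold = bh,
             flagged = flagged, stringsAsFactors = FALSE)
}

#' Write differential-expression results as TSV
#'
#' @param de a [nb_wald_test()] result.
#' @param path file path.
#' @export
write_de_tsv <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an association scan as a Table-2-style TSV
#'
#' Columns: RNA, Score, r, t, P, adj_sig_thresh.
#'
#' @param assoc a [pearson_scan()] result.
#' @param score_name the response name to repeat in the `Score` column.
#' @param path file path.
#' @export
write_assoc_tsv <- function(assoc, score_name, path) {
  out <- data.frame(RNA = assoc$feature_id, Score = score_name,
                    r = assoc$r, t = assoc$t, P = assoc$p_value,
                    adj_sig_thresh = assoc$bh_threshold)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
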