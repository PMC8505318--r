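#' Collapse highly similar piRNA sequences into wiRNA clusters
#'
#' Computes pairwise global-alignment identity (matches / alignment
#' length) between piRNA sequences, runs hierarchical clustering on
#' `1 - identity` and cuts at `1 - identity_threshold`. With the default
#' single linkage the clusters are exactly the connected components of
#' the graph whose edges join pairs at or above the identity threshold.
#'
#' @param sequences named character vector of nucleotide sequences over
#'   `A,C,G,T,U,N` (U is treated as T).
#' @param identity_threshold minimum pairwise identity for two sequences
#'   to be linked, in (0, 1].
#' @param linkage hclust agglomeration method (default `"single"`).
#' @return data.frame with columns `feature_id`, `cluster_id`
#'   (`wiRNA_k`, numbered in order of first appearance).
#' @export
cluster_pirnas <- function(sequences, identity_threshold = 0.90,
                           linkage = "single") {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop_bad_arg("sequences must be uniquely named by feature id")
  if (any(!nzchar(sequences)) || any(is.na(sequences)))
    stop_bad_arg("empty sequence")
  if (identity_threshold <= 0 || identity_threshold > 1)
    stop_bad_arg("identity_threshold must be in (0, 1]")
  seqs <- toupper(gsub("U", "T", sequences))
  if (any(grepl("[^ACGTN]", seqs)))
    stop_bad_arg("sequences must be over the alphabet A,C,G,T,U,N")
  n <- length(seqs)
  cl <- if (n == 1) 1L else {
    idm <- pairwise_identity(seqs)
    hc <- stats::hclust(stats::as.dist(1 - idm), method = linkage)
    stats::cutree(hc, h = 1 - identity_threshold)
  }
  # renumber clusters in order of first appearance
  cl <- as.integer(factor(cl, levels = unique(cl)))
  data.frame(feature_id = names(sequences),
             cluster_id = sprintf("wiRNA_%d", cl),
             stringsAsFactors = FALSE)
}

# Pairwise global-alignment identity matrix: matches / alignment length
# (gapped columns count in the denominator), under unit-cost global
# (Levenshtein) alignment with end gaps penalized. With substitutions s,
# insertions i and deletions d transforming sequence a (length la) into
# b: matches = la - s - d and alignment length = matches + s + d + i.
pairwise_identity <- function(seqs) {
  d <- utils::adist(seqs, counts = TRUE)
  cnt <- attr(d, "counts")
  la <- matrix(nchar(seqs), length(seqs), length(seqs))
  matches <- la - cnt[, , "sub"] - cnt[, , "del"]
  alen <- matches + cnt[, , "sub"] + cnt[, , "del"] + cnt[, , "ins"]
  idm <- matches / alen
  dimnames(idm) <- list(names(seqs), names(seqs))
  idm
}

#' Sum piRNA counts within wiRNA clusters
#'
#' piRNA rows belonging to the same cluster are summed into a single
#' `wiRNA_k` row (category `wiRNA`); all non-piRNA rows pass through
#' untouched. Per-sample total piRNA counts are conserved exactly.
#'
#' @param m an [ncrna_counts()].
#' @param clusters data.frame from [cluster_pirnas()].
#' @return an [ncrna_counts()] with piRNA rows collapsed.
#' @export
collapse_pirna_clusters <- function(m, clusters) {
  stopifnot(inherits(m, "ncrna_counts"))
  is_pi <- m$features$category == "piRNA"
  miss <- setdiff(m$features$feature_id[is_pi], clusters$feature_id)
  if (length(miss))
    stop_bad_arg("no cluster assignment for: ", paste(head(miss), collapse = ", "))
  keep <- m$counts[!is_pi, , drop = FALSE]
  cl <- clusters$cluster_id[match(m$features$feature_id[is_pi],
                                  clusters$feature_id)]
  pi_counts <- m$counts[is_pi, , drop = FALSE]
  summed <- rowsum(pi_counts, cl, reorder = FALSE)
  out <- rbind(keep, summed)
  ncrna_counts(out, c(m$features$category[!is_pi],
                      rep("wiRNA", nrow(summed))))
}

#' Remove low-abundance features
#'
#' A feature is removed iff its counts summed over all samples are below
#' `min_fraction` of the summed counts of all features in its RNA
#' category (the 0.01% rule with the default). Filtering decisions are
#' independent per category.
#'
#' @param m an [ncrna_counts()].
#' @param min_fraction removal threshold as a fraction of the category
#'   total (default 1e-4 = 0.01%).
#' @return filtered [ncrna_counts()]; the number of removed features is
#'   attached as attribute `n_removed`.
#' @export
filter_low_counts <- function(m, min_fraction = 1e-4) {
  stopifnot(inherits(m, "ncrna_counts"))
  if (nrow(m$counts) == 0 || ncol(m$counts) == 0)
    stop_bad_arg("empty count matrix")
  if (min_fraction < 0) stop_bad_arg("min_fraction must be >= 0")
  totals <- rowSums(m$counts)
  cat_total <- tapply(totals, m$features$category, sum)
  keep <- totals >= min_fraction * cat_total[m$features$category]
  out <- subset_features(m, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Total sum scaling
#'
#' Divides each sample's counts by its total so every column sums to 1.
#'
#' @param m an [ncrna_counts()] or a numeric matrix (features x samples).
#' @return matrix of per-sample proportions.
#' @export
tss_normalize <- function(m) {
  counts <- if (inherits(m, "ncrna_counts")) m$counts else as.matrix(m)
  tot <- colSums(counts)
  if (any(tot == 0))
    stop_bad_arg("sample(s) with zero total counts: ",
                 paste(colnames(counts)[tot == 0], collapse = ", "))
  sweep(counts, 2, tot, "/")
}

#' Inverse hyperbolic sine transform
#'
#' Elementwise `log(x + sqrt(x^2 + 1))`; monotone, maps 0 to 0, and
#' compresses the right tail like a log without needing a pseudocount.
#'
#' @param x numeric vector or matrix of finite values.
#' @return transformed values, same shape.
#' @export
asinh_transform <- function(x) {
  if (any(!is.finite(x))) stop_bad_arg("inputs must be finite")
  asinh(x)
}

#' Full preprocessing pipeline: cluster, filter, normalize, transform
#'
#' Applies the fixed stage order: piRNA sequence clustering into wiRNAs
#' (skipped when no piRNA sequences are available), low-abundance
#' filtering per category, total sum scaling, and the inverse hyperbolic
#' sine transform. Refuses non-integer input so already-processed
#' matrices are not processed twice.
#'
#' @param m an [ncrna_counts()].
#' @param identity_threshold,linkage passed to [cluster_pirnas()].
#' @param min_fraction passed to [filter_low_counts()].
#' @return list with `matrix` (transformed features x samples), `counts`
#'   (the collapsed+filtered [ncrna_counts()]), and `clusters` (the
#'   piRNA-to-wiRNA map, or NULL when clustering was skipped).
#' @export
preprocess_counts <- function(m, identity_threshold = 0.90,
                              min_fraction = 1e-4, linkage = "single") {
  stopifnot(inherits(m, "ncrna_counts"))
  if (any(m$counts != round(m$counts)))
    stop_bad_arg("counts are not integers; input looks already processed")
  is_pi <- m$features$category == "piRNA"
  clusters <- NULL
  if (any(is_pi) && any(!is.na(m$features$sequence[is_pi]))) {
    seqs <- m$features$sequence[is_pi]
    names(seqs) <- m$features$feature_id[is_pi]
    if (any(is.na(seqs)))
      stop_bad_arg("some piRNA features lack sequences")
    clusters <- cluster_pirnas(seqs, identity_threshold, linkage)
    m <- collapse_pirna_clusters(m, clusters)
  }
  m <- filter_low_counts(m, min_fraction)
  list(matrix = asinh_transform(tss_normalize(m)), counts = m,
       clusters = clusters)
}
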