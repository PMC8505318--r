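#' Small-RNA count matrix container
#'
#' A light container for a features x samples matrix of non-negative
#' integer read counts, with each feature tagged with its RNA category
#' (miRNA, snoRNA, piRNA or, after clustering, wiRNA) and an optional
#' nucleotide sequence (used for piRNA cluster collapsing).
#'
#' @param counts numeric matrix, features x samples, with unique rownames
#'   (feature ids) and colnames (sample ids); values must be non-negative
#'   integers.
#' @param categories character vector (one per feature, or named by
#'   feature id) with values in `miRNA`, `snoRNA`, `piRNA`, `wiRNA`.
#' @param sequences optional character vector of nucleotide sequences,
#'   named by feature id (typically only piRNAs carry sequences).
#' @return an object of class `ncrna_counts` with elements `counts`
#'   (integer matrix) and `features` (data.frame of `feature_id`,
#'   `category`, `sequence`).
#' @export
ncrna_counts <- function(counts, categories, sequences = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_bad_arg("counts must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop_bad_arg("duplicate feature ids")
  if (anyDuplicated(colnames(counts)))
    stop_bad_arg("duplicate sample ids")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_bad_arg("counts must be non-negative integers")
  storage.mode(counts) <- "double"
  if (!is.null(names(categories))) categories <- categories[rownames(counts)]
  categories <- as.character(categories)
  if (length(categories) != nrow(counts))
    stop_bad_arg("need one category per feature")
  bad <- setdiff(unique(categories), c("miRNA", "snoRNA", "piRNA", "wiRNA"))
  if (length(bad))
    stop_bad_arg("unknown RNA categories: ", paste(bad, collapse = ", "))
  seqs <- rep(NA_character_, nrow(counts))
  if (!is.null(sequences)) {
    if (is.null(names(sequences)))
      stop_bad_arg("sequences must be named by feature id")
    hit <- match(rownames(counts), names(sequences))
    seqs[!is.na(hit)] <- unname(sequences[hit[!is.na(hit)]])
  }
  structure(
    list(counts = counts,
         features = data.frame(feature_id = rownames(counts),
                               category = categories,
                               sequence = seqs,
                               stringsAsFactors = FALSE)),
    class = "ncrna_counts")
}

#' @export
print.ncrna_counts <- function(x, ...) {
  cat("ncrna_counts:", nrow(x$counts), "features x", ncol(x$counts),
      "samples\n")
  print(table(x$features$category))
  invisible(x)
}

#' @export
dim.ncrna_counts <- function(x) dim(x$counts)

subset_features <- function(m, keep) {
  stopifnot(inherits(m, "ncrna_counts"))
  seqs <- m$features$sequence
  names(seqs) <- m$features$feature_id
  ncrna_counts(m$counts[keep, , drop = FALSE],
               m$features$category[keep],
               seqs[!is.na(seqs)])
}

#' Write / read a count matrix as TSV
#'
#' The TSV has columns `feature_id`, `category`, then one column per
#' sample. Sequences, when present, travel separately as FASTA
#' ([write_sequences_fasta()]).
#'
#' @param m an [ncrna_counts()] object.
#' @param path file path.
#' @return `write_counts_tsv` returns `path` invisibly; `read_counts_tsv`
#'   returns an `ncrna_counts`.
#' @export
write_counts_tsv <- function(m, path) {
  stopifnot(inherits(m, "ncrna_counts"))
  df <- data.frame(feature_id = m$features$feature_id,
                   category = m$features$category,
                   m$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param sequences_fasta optional FASTA of feature sequences to attach.
#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path, sequences_fasta = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(counts) <- df$feature_id
  seqs <- NULL
  if (!is.null(sequences_fasta)) {
    ss <- Biostrings::readDNAStringSet(sequences_fasta)
    seqs <- as.character(ss)
  }
  ncrna_counts(counts, df$category, seqs)
}

#' Write feature sequences as FASTA
#'
#' @param m an [ncrna_counts()] object with at least one sequence.
#' @param path file path.
#' @export
write_sequences_fasta <- function(m, path) {
  stopifnot(inherits(m, "ncrna_counts"))
  has <- !is.na(m$features$sequence)
  if (!any(has)) stop_bad_arg("no sequences to write")
  ss <- Biostrings::DNAStringSet(gsub("U", "T", m$features$sequence[has]))
  names(ss) <- m$features$feature_id[has]
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write / read the per-sample cohort table as CSV
#'
#' One row per sample, with participant-level fields repeated.
#'
#' @param cohort an `mtbi_cohort` (see [generate_cohort()]).
#' @param path file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "mtbi_cohort"))
  df <- merge(cohort$samples, cohort$participants, by = "participant_id",
              sort = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) read.csv(path, check.names = FALSE)

#' Write / read a feature panel as JSON
#'
#' @param panel a `feature_panel` data.frame (see [union_candidates()]).
#' @param path file path.
#' @export
write_panel_json <- function(panel, path) {
  jsonlite::write_json(panel, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_panel_json
#' @export
read_panel_json <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(df) <- c("feature_panel", class(df))
  df
}
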