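#' Enumerate the k-mer vocabulary
#'
#' @param k word length (k >= 1).
#' @return character vector of the `4^k` k-mers over `{A,C,G,T}` in
#'   lexicographic order — the fixed feature order of the classifier.
#' @export
kmer_vocabulary <- function(k) {
  if (length(k) != 1 || k < 1 || k != round(k)) stop("k must be an integer >= 1")
  Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
}

#' k-mer frequency featurization
#'
#' Represents each sequence as the frequency vector of its length-`k`
#' windows (step 1). Windows containing any non-ACGT symbol (N, R, Y, S,
#' W, ...) are discarded; frequencies are counts divided by the number of
#' retained windows, so rows sum to 1 for unambiguous input and an
#' all-ambiguous sequence yields a zero row. Input case is ignored.
#'
#' @param x sequences: [Biostrings::DNAStringSet] or character vector.
#' @param k word length (default 4, giving 256 features).
#' @return numeric matrix, one row per sequence, columns named by
#'   [kmer_vocabulary()]; rownames are sequence ids when available.
#' @export
kmer_featurize <- function(x, k = 4L) {
  if (length(k) != 1 || k < 1 || k != round(k)) stop("k must be an integer >= 1")
  x <- as_dna(x)
  if (any(Biostrings::width(x) < k))
    stop("sequence(s) shorter than k: ",
         paste(head(which(Biostrings::width(x) < k), 5), collapse = ", "))
  counts <- Biostrings::oligonucleotideFrequency(x, width = k)
  tot <- rowSums(counts)
  out <- counts / pmax(tot, 1)  # zero rows stay zero
  rownames(out) <- names(x)
  out
}

#' Build a labeled feature matrix from positive and negative sets
#'
#' Rows keep input order: positives (label 1) first, then negatives
#' (label 0). Sequences shorter than `k` are not featurizable; they are
#' excluded and listed in the `skipped` element rather than silently
#' dropped.
#'
#' @param positives,negatives sequence sets
#'   ([Biostrings::DNAStringSet] or character).
#' @param k word length (default 4).
#' @return an object of class `kmer_matrix`: list with `x` (feature
#'   matrix), `labels` (integer 0/1), `ids`, `k` and `skipped`
#'   (data.frame of excluded ids and reasons).
#' @export
kmer_matrix <- function(positives, negatives, k = 4L) {
  positives <- as_dna(positives); negatives <- as_dna(negatives)
  if (!length(positives) || !length(negatives))
    stop("both sequence sets must be non-empty")
  if (is.null(names(positives)))
    names(positives) <- sprintf("pos_%04d", seq_along(positives))
  if (is.null(names(negatives)))
    names(negatives) <- sprintf("neg_%04d", seq_along(negatives))
  all_seqs <- c(positives, negatives)
  labels <- c(rep(1L, length(positives)), rep(0L, length(negatives)))
  short <- Biostrings::width(all_seqs) < k
  skipped <- data.frame(id = names(all_seqs)[short],
                        reason = rep(sprintf("length < k (%d)", k), sum(short)),
                        stringsAsFactors = FALSE)
  keep <- !short
  out <- list(x = kmer_featurize(all_seqs[keep], k = k),
              labels = labels[keep], ids = names(all_seqs)[keep],
              k = as.integer(k), skipped = skipped)
  class(out) <- "kmer_matrix"
  out
}

#' @export
print.kmer_matrix <- function(x, ...) {
  cat(sprintf("k-mer feature matrix: %d rows x %d features (k = %d); %d pos / %d neg",
              nrow(x$x), ncol(x$x), x$k, sum(x$labels == 1), sum(x$labels == 0)))
  if (nrow(x$skipped)) cat(sprintf("; %d skipped", nrow(x$skipped)))
  cat("\n")
  invisible(x)
}

#' Write a feature matrix as TSV
#'
#' Columns: id, label, then the named k-mer frequencies.
#'
#' @param m a [kmer_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_kmer_tsv <- function(m, path) {
  stopifnot(inherits(m, "kmer_matrix"))
  df <- data.frame(id = m$ids, label = m$labels, m$x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
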