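#' Read a FASTA file
#'
#' Thin, validating wrapper around [Biostrings::readDNAStringSet()].
#' Record order is preserved, wrapped sequence lines are joined and bases
#' are uppercased. Structural problems are reported with a line number;
#' duplicate record ids are an error.
#'
#' @param path path to a FASTA file.
#' @return a named [Biostrings::DNAStringSet]; names hold the full header
#'   line (id plus description).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty)) stop("FASTA format error: empty file: ", path)
  if (!startsWith(lines[nonempty[1]], ">"))
    stop(sprintf("FASTA format error at line %d: expected '>' header",
                 nonempty[1]))
  hdr <- which(startsWith(lines, ">"))
  ends <- c(hdr[-1] - 1L, length(lines))
  for (i in seq_along(hdr)) {
    body <- lines[seq.int(hdr[i] + 1L, length.out = max(0L, ends[i] - hdr[i]))]
    if (!any(nzchar(trimws(body))))
      stop(sprintf("FASTA format error at line %d: record '%s' has no sequence",
                   hdr[i], sub("^>", "", lines[hdr[i]])))
  }
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  x
}

#' Write sequences as FASTA
#'
#' @param x a [Biostrings::DNAStringSet] or named character vector.
#' @param path output file.
#' @param width line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  Biostrings::writeXStringSet(as_dna(x), path, width = width)
  invisible(path)
}

#' Filter records by minimum length
#'
#' The draft-assembly convention applied here keeps contigs at or above the
#' threshold (boundary inclusive by default).
#'
#' @param x a [Biostrings::DNAStringSet] or character vector.
#' @param min_len minimum retained length in bp (default 500).
#' @param inclusive if `TRUE` (default) keep `length >= min_len`, else
#'   strictly greater.
#' @return the retained records, input order preserved.
#' @export
filter_min_length <- function(x, min_len = 500L, inclusive = TRUE) {
  stopifnot(min_len >= 0)
  x <- as_dna(x)
  w <- Biostrings::width(x)
  x[if (inclusive) w >= min_len else w > min_len]
}

#' Assembly summary statistics
#'
#' Computes the contig-level summary reported for draft assemblies:
#' contig count, length extremes, total length, N50 and GC/AT percentages.
#' N50 is the length at which the cumulative sum over descending contig
#' lengths first reaches at least half the total (inclusive at an exact
#' tie). Ambiguous bases are excluded from the GC/AT denominators, so
#' `gc_percent + at_percent == 100` whenever any unambiguous base exists.
#'
#' @param x a [Biostrings::DNAStringSet] or character vector of contigs.
#' @return an object of class `assembly_stats`: a list with `n_contigs`,
#'   `min_length`, `max_length`, `total_length`, `n50`, `gc_percent`,
#'   `at_percent`.
#' @export
assembly_stats <- function(x) {
  x <- as_dna(x)
  if (!length(x)) stop("assembly_stats() needs at least one record")
  w <- Biostrings::width(x)
  freq <- Biostrings::letterFrequency(x, c("A", "C", "G", "T"))
  gc <- sum(freq[, c("C", "G")])
  acgt <- sum(freq)
  out <- list(
    n_contigs = length(x),
    min_length = min(w),
    max_length = max(w),
    total_length = sum(as.numeric(w)),
    n50 = n50(w),
    gc_percent = if (acgt > 0) 100 * gc / acgt else NaN,
    at_percent = if (acgt > 0) 100 * (acgt - gc) / acgt else NaN)
  structure(out, class = "assembly_stats")
}

#' N50 of a set of contig lengths
#'
#' @param lengths integer vector of contig lengths.
#' @return the N50 length.
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) >= 1, all(lengths >= 0))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("Assembly statistics\n")
  cat(sprintf("  contigs:      %s\n", format(x$n_contigs, big.mark = ",")))
  cat(sprintf("  min / max:    %s / %s bp\n",
              format(x$min_length, big.mark = ","),
              format(x$max_length, big.mark = ",")))
  cat(sprintf("  total length: %s bp\n",
              format(x$total_length, big.mark = ",")))
  cat(sprintf("  N50:          %s bp\n", format(x$n50, big.mark = ",")))
  cat(sprintf("  GC / AT:      %.2f%% / %.2f%%\n",
              x$gc_percent, x$at_percent))
  invisible(x)
}

#' Write intervals as BED6
#'
#' @param df data.frame with columns `contig_id`, `start`, `end` (0-based
#'   half-open) and optionally `name`, `score`, `strand`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(df, path) {
  stopifnot(all(c("contig_id", "start", "end") %in% names(df)),
            all(df$end > df$start), all(df$start >= 0))
  bed <- data.frame(
    chrom = df$contig_id, start = df$start, end = df$end,
    name = df$name %||% ".",
    score = df$score %||% 0,
    strand = df$strand %||% ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
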