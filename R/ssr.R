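#' SSR mining configuration
#'
#' Default thresholds follow the common survey convention: mononucleotide
#' runs of at least 10 bases; 2-6 nt motifs with at least 5 repeats.
#'
#' @param min_mono_length minimum run length (bases) for mononucleotide
#'   loci.
#' @param min_repeats minimum repeat count for 2-6 nt motifs.
#' @param motif_lengths motif lengths searched (subset of 1:6).
#' @return object of class `ssr_config`.
#' @export
ssr_config <- function(min_mono_length = 10L, min_repeats = 5L,
                       motif_lengths = 1:6) {
  stopifnot(min_mono_length >= 1, min_repeats >= 1,
            all(motif_lengths %in% 1:6))
  structure(list(min_mono_length = as.integer(min_mono_length),
                 min_repeats = as.integer(min_repeats),
                 motif_lengths = sort(as.integer(motif_lengths))),
            class = "ssr_config")
}

# TRUE when motif is not itself a tandem repetition of a shorter motif.
is_primitive <- function(motif) {
  m <- nchar(motif)
  if (m == 1) return(TRUE)
  for (d in seq_len(m - 1)) {
    if (m %% d == 0 && strrep(substr(motif, 1, d), m / d) == motif)
      return(FALSE)
  }
  TRUE
}

#' Canonical motif class
#'
#' The lexicographically smallest string among all rotations of the motif
#' and of its reverse complement — the label used to group equivalent
#' motifs (e.g. `"TA"`, `"AT"` and their complements all map to `"AT"`).
#'
#' @param motif character vector of 1-6 nt ACGT motifs.
#' @return character vector of canonical motif classes.
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(mo) {
    mo <- toupper(mo)
    if (!grepl("^[ACGT]{1,6}$", mo))
      stop("motif must be 1-6 nt over ACGT: ", mo)
    m <- nchar(mo)
    rots <- function(s) vapply(seq_len(m) - 1L, function(r)
      paste0(substr(s, r + 1, m), substr(s, 1, r)), character(1))
    min(c(rots(mo), rots(revcomp_chr(mo))))
  }, character(1), USE.NAMES = FALSE)
}

# All maximal perfect tandem runs of period m in character vector x.
# Returns start (1-based), repeat count and motif; truncates trailing
# partial repeats so locus length is motif length x count.
period_runs <- function(x, m, acgt_ok) {
  n <- length(x)
  if (n < 2 * m) return(NULL)
  idx <- seq_len(n - m)
  good <- (x[idx] == x[idx + m]) & acgt_ok[idx] & acgt_ok[idx + m]
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= m  # need at least 2 full units
  if (!any(keep)) return(NULL)
  data.frame(start = starts[keep],
             count = (r$lengths[keep] + m) %/% m,
             stringsAsFactors = FALSE)
}

#' Find microsatellite (SSR) loci
#'
#' Detects maximal perfect tandem repeats of primitive 1-6 nt motifs. A
#' run qualifies when it is a mononucleotide run of at least
#' `min_mono_length` bases, or a 2-6 nt motif repeated at least
#' `min_repeats` times. Runs are broken at ambiguous bases. When
#' qualifying runs of different periods overlap, the longer run wins,
#' ties go to the shorter motif, then to the leftmost start, and every
#' genomic position belongs to at most one reported locus.
#'
#' @param x contigs as a [Biostrings::DNAStringSet], character vector,
#'   or a single string.
#' @param config an [ssr_config()].
#' @return data.frame: `contig_id`, `start`, `end` (0-based half-open),
#'   `motif`, `repeat_count`, `length`, `motif_class`; sorted by
#'   (contig, start).
#' @export
find_ssrs <- function(x, config = ssr_config()) {
  x <- as_dna(x)
  if (is.null(names(x))) names(x) <- sprintf("seq_%03d", seq_along(x))
  out <- lapply(seq_along(x), function(ci)
    find_ssrs_one(as.character(x[[ci]]), names(x)[ci], config))
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) {
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      repeat_count = integer(0), length = integer(0),
                      motif_class = character(0), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

find_ssrs_one <- function(seq, contig_id, config) {
  xs <- strsplit(seq, "")[[1]]
  n <- length(xs)
  acgt_ok <- xs %in% c("A", "C", "G", "T")
  cand <- list()
  for (m in config$motif_lengths) {
    runs <- period_runs(xs, m, acgt_ok)
    if (is.null(runs)) next
    motifs <- substring(seq, runs$start, runs$start + m - 1L)
    prim <- vapply(motifs, is_primitive, logical(1), USE.NAMES = FALSE)
    qual <- if (m == 1) runs$count >= config$min_mono_length
            else runs$count >= config$min_repeats
    keep <- prim & qual
    if (!any(keep)) next
    cand[[length(cand) + 1L]] <- data.frame(
      start = runs$start[keep], m = m, motif = motifs[keep],
      count = runs$count[keep], len = m * runs$count[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(cand)) return(NULL)
  cand <- do.call(rbind, cand)
  # precedence: longer run, then shorter motif, then leftmost
  cand <- cand[order(-cand$len, cand$m, cand$start), ]
  taken <- logical(n)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- cand$start[i]:(cand$start[i] + cand$len[i] - 1L)
    if (!any(taken[span])) {
      taken[span] <- TRUE
      keep[i] <- TRUE
    }
  }
  cand <- cand[keep, ]
  cand <- cand[order(cand$start), ]
  data.frame(contig_id = contig_id, start = cand$start - 1L,
             end = cand$start - 1L + cand$len, motif = cand$motif,
             repeat_count = cand$count, length = cand$len,
             motif_class = canonical_motif(cand$motif),
             stringsAsFactors = FALSE)
}

#' Summarize SSR loci
#'
#' Counts and percentage shares per motif length plus the overall
#' density, in kb of assembly per microsatellite locus. Percentages are
#' rounded half-up to 2 decimals, density to 1 decimal, matching the
#' printed precision of published survey tables.
#'
#' @param loci data.frame from [find_ssrs()].
#' @param assembly_total_length total assembly length in bp.
#' @return object of class `ssr_summary`: list with `per_length`
#'   (data.frame motif_length / n / percent), `per_motif` (table of
#'   canonical classes), `total`, `density_kb` (`NA` when no loci).
#' @export
ssr_summary <- function(loci, assembly_total_length) {
  stopifnot(assembly_total_length > 0)
  total <- nrow(loci)
  ml <- if (total) nchar(loci$motif) else integer(0)
  counts <- vapply(1:6, function(m) sum(ml == m), numeric(1))
  per_length <- data.frame(
    motif_length = c("mono", "di", "tri", "tetra", "penta", "hexa"),
    n = counts,
    percent = if (total) round_half_up(100 * counts / total, 2) else
      rep(NA_real_, 6))
  density <- if (total) {
    round_half_up((assembly_total_length / 1000) / total, 1)
  } else NA_real_
  structure(list(per_length = per_length,
                 per_motif = if (total) sort(table(loci$motif_class),
                                             decreasing = TRUE) else table(character(0)),
                 total = total, assembly_total_length = assembly_total_length,
                 density_kb = density),
            class = "ssr_summary")
}

#' @export
print.ssr_summary <- function(x, ...) {
  cat("Microsatellite summary\n")
  df <- x$per_length
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-6s %8d  %6.2f%%\n", df$motif_length[i], df$n[i],
                df$percent[i]))
  cat(sprintf("  total  %8d loci\n", x$total))
  if (!is.na(x$density_kb))
    cat(sprintf("  density: %.1f kb/locus over %s bp\n", x$density_kb,
                format(x$assembly_total_length, big.mark = ",")))
  else cat("  density: undefined (no loci)\n")
  invisible(x)
}

#' Write SSR loci as BED4
#'
#' Name column is `motif:count`.
#'
#' @param loci data.frame from [find_ssrs()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ssr_bed <- function(loci, path) {
  bed <- data.frame(chrom = loci$contig_id, start = loci$start,
                    end = loci$end,
                    name = sprintf("%s:%d", loci$motif, loci$repeat_count))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
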