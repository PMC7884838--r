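#' Genome scan configuration
#'
#' @param window_length sliding-window length in nt (default 70).
#' @param step window step in nt (default 7; use 1 for exhaustive scans).
#' @param probability_threshold minimum classifier probability for a
#'   window to become a hit (default 0.95).
#' @param both_strands scan the reverse complement too (default `TRUE`).
#' @param merge_gap maximum gap (nt) between same-strand hits merged into
#'   one locus (default 0 = overlap or abut).
#' @return object of class `scan_config`.
#' @export
scan_config <- function(window_length = 70L, step = 7L,
                        probability_threshold = 0.95,
                        both_strands = TRUE, merge_gap = 0L) {
  stopifnot(window_length >= 1, step >= 1, step <= window_length,
            probability_threshold > 0, probability_threshold < 1,
            merge_gap >= 0)
  structure(list(window_length = as.integer(window_length),
                 step = as.integer(step),
                 probability_threshold = probability_threshold,
                 both_strands = isTRUE(both_strands),
                 merge_gap = as.integer(merge_gap)),
            class = "scan_config")
}

#' Window start coordinates for one contig
#'
#' Starts at 0, `step`, `2*step`, ...; only windows lying fully inside
#' the contig are produced, so contigs shorter than the window yield none.
#'
#' @param contig_length contig length in bp.
#' @param config a [scan_config()].
#' @return integer vector of 0-based window starts.
#' @export
scan_windows <- function(contig_length, config = scan_config()) {
  if (contig_length < config$window_length) return(integer(0))
  seq.int(0L, contig_length - config$window_length, by = config$step)
}

#' Scan contigs with a trained classifier
#'
#' Every window is featurized exactly as the training data (k-mer
#' frequencies with ambiguous windows dropped); windows whose probability
#' reaches `probability_threshold` are reported as hits. The reverse
#' strand is scanned on the reverse complement with coordinates mapped
#' back to the forward strand. Windows with no valid k-mer (all
#' ambiguous) are skipped.
#'
#' @param contigs a [Biostrings::DNAStringSet] (or character vector).
#' @param model a [mirna_classifier()] whose `k` matches `k`.
#' @param config a [scan_config()].
#' @param k featurizer word length (default 4); must equal `model$k`.
#' @param chunk_size windows classified per batch (memory control).
#' @return data.frame of hits: `contig_id`, `start`, `end` (0-based
#'   half-open, forward coordinates), `strand`, `probability`.
#' @export
scan_genome <- function(contigs, model, config = scan_config(), k = 4L,
                        chunk_size = 20000L) {
  stopifnot(inherits(model, "mirna_classifier"))
  if (model$k != k)
    stop(sprintf("model was trained with k = %d but featurizer k = %d",
                 model$k, k))
  contigs <- as_dna(contigs)
  if (is.null(names(contigs)))
    names(contigs) <- sprintf("contig_%03d", seq_along(contigs))
  strands <- if (config$both_strands) c("+", "-") else "+"
  hits <- list()
  for (ci in seq_along(contigs)) {
    L <- Biostrings::width(contigs)[ci]
    starts0 <- scan_windows(L, config)
    if (!length(starts0)) next
    for (strand in strands) {
      seqs <- if (strand == "+") contigs[[ci]] else
        Biostrings::reverseComplement(contigs[[ci]])
      wins <- Biostrings::extractAt(
        seqs, IRanges::IRanges(start = starts0 + 1L,
                               width = config$window_length))
      for (block in split(seq_along(starts0),
                          ceiling(seq_along(starts0) / chunk_size))) {
        feats <- kmer_featurize(wins[block], k = k)
        valid <- rowSums(feats) > 0
        if (!any(valid)) next
        p <- predict(model, feats[valid, , drop = FALSE])
        keep <- p >= config$probability_threshold
        if (!any(keep)) next
        st <- starts0[block][valid][keep]
        if (strand == "-") st <- L - st - config$window_length
        hits[[length(hits) + 1L]] <- data.frame(
          contig_id = names(contigs)[ci], start = st,
          end = st + config$window_length, strand = strand,
          probability = p[keep], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      probability = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$contig_id, out$strand, out$start), ]
  rownames(out) <- NULL
  out
}

#' Merge window hits into candidate loci
#'
#' Same-strand hits on one contig whose intervals overlap or lie within
#' `merge_gap` of each other collapse into a single candidate locus
#' spanning their union. Window counts are conserved: the
#' `n_supporting_windows` column sums to the number of input hits.
#'
#' @param hits data.frame from [scan_genome()].
#' @param config a [scan_config()] (for `merge_gap`).
#' @param min_windows report only loci supported by at least this many
#'   windows (default 1 = report all).
#' @return data.frame of loci: `locus_id`, `contig_id`, `start`, `end`,
#'   `strand`, `max_probability`, `n_supporting_windows`.
#' @export
merge_hits <- function(hits, config = scan_config(), min_windows = 1L) {
  empty <- data.frame(locus_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), max_probability = numeric(0),
                      n_supporting_windows = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)
  hits <- hits[order(hits$contig_id, hits$strand, hits$start), ]
  loci <- list()
  for (grp in split(hits, paste(hits$contig_id, hits$strand))) {
    # chain: new group whenever a hit starts beyond the running end + gap
    run_end <- cummax_end <- NULL
    starts <- grp$start; ends <- grp$end
    grp_id <- integer(nrow(grp)); cur <- 1L; grp_id[1] <- 1L
    hi <- ends[1]
    if (nrow(grp) > 1) for (i in 2:nrow(grp)) {
      if (starts[i] > hi + config$merge_gap) cur <- cur + 1L
      grp_id[i] <- cur
      hi <- max(hi, ends[i])
    }
    for (g in split(seq_len(nrow(grp)), grp_id)) {
      loci[[length(loci) + 1L]] <- data.frame(
        contig_id = grp$contig_id[1], start = min(starts[g]),
        end = max(ends[g]), strand = grp$strand[1],
        max_probability = max(grp$probability[g]),
        n_supporting_windows = length(g), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, loci)
  out <- out[order(out$contig_id, out$strand, out$start), ]
  out <- cbind(locus_id = sprintf("locus_%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[out$n_supporting_windows >= min_windows, ]
}

#' Write candidate loci as BED6
#'
#' Score column is probability x 1000, capped at 1000.
#'
#' @param loci data.frame from [merge_hits()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  df <- data.frame(contig_id = loci$contig_id, start = loci$start,
                   end = loci$end, name = loci$locus_id,
                   score = pmin(1000, round(loci$max_probability * 1000)),
                   strand = loci$strand)
  write_bed6(df, path)
}

#' Write candidate loci as GFF3
#'
#' @param loci data.frame from [merge_hits()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_loci_gff3 <- function(loci, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(loci)) {
    rows <- sprintf("%s\tpremirscan\tpre_miRNA\t%d\t%d\t%.4f\t%s\t.\tID=%s;windows=%d",
                    loci$contig_id, loci$start + 1L, loci$end,
                    loci$max_probability, loci$strand, loci$locus_id,
                    loci$n_supporting_windows)
    writeLines(rows, con)
  }
  invisible(path)
}

#' Extract locus sequences from contigs
#'
#' @param loci data.frame from [merge_hits()].
#' @param contigs the scanned [Biostrings::DNAStringSet].
#' @return a named [Biostrings::DNAStringSet] of forward-strand locus
#'   sequences.
#' @export
locus_sequences <- function(loci, contigs) {
  contigs <- as_dna(contigs)
  out <- Biostrings::DNAStringSet(vapply(seq_len(nrow(loci)), function(i) {
    s <- Biostrings::subseq(contigs[[loci$contig_id[i]]],
                            start = loci$start[i] + 1L, end = loci$end[i])
    as.character(s)
  }, character(1)))
  names(out) <- loci$locus_id
  out
}
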