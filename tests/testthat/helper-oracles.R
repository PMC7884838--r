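# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's code paths: plain loops and
# substring arithmetic only.

# N50 by prefix enumeration over the sorted multiset.
oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  total <- sum(s)
  acc <- 0
  for (v in s) {
    acc <- acc + v
    if (acc >= total / 2) return(v)
  }
  NA
}

# Maximal perfect tandem repeats by direct substring comparison, with the
# same published thresholds and precedence rules (longer run, shorter
# motif, leftmost; one locus per position).
oracle_find_ssrs <- function(seq, min_mono = 10L, min_rep = 5L) {
  n <- nchar(seq)
  cand <- list()
  for (m in 1:6) {
    if (n < 2 * m) next
    p_all <- 1:(n - 2 * m + 1)
    u1 <- substring(seq, p_all, p_all + m - 1)
    u2 <- substring(seq, p_all + m, p_all + 2 * m - 1)
    clean <- !grepl("[^ACGT]", u1) & !grepl("[^ACGT]", u2)
    # maximal: no single-base periodic extension to the left
    left <- substring(seq, p_all - 1, p_all - 1)
    lper <- substring(seq, p_all + m - 1, p_all + m - 1)
    maximal <- p_all == 1 | left != lper | grepl("[^ACGT]", left)
    starts <- p_all[u1 == u2 & clean & maximal]
    for (p in starts) {
      unit <- substring(seq, p, p + m - 1)
      prim <- TRUE
      for (d in seq_len(m - 1))
        if (m %% d == 0 &&
            strrep(substring(unit, 1, d), m / d) == unit) prim <- FALSE
      if (!prim) next
      cnt <- 2L
      repeat {
        nxt <- substring(seq, p + cnt * m, p + (cnt + 1) * m - 1)
        if (nchar(nxt) < m || nxt != unit || grepl("[^ACGT]", nxt)) break
        cnt <- cnt + 1L
      }
      ok <- if (m == 1) cnt >= min_mono else cnt >= min_rep
      if (ok)
        cand[[length(cand) + 1L]] <-
          data.frame(start = p, m = m, motif = unit, count = cnt,
                     len = m * cnt, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand))
    return(data.frame(start = integer(0), m = integer(0),
                      motif = character(0), count = integer(0),
                      len = integer(0)))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$len, cand$m, cand$start), ]
  taken <- logical(n)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- cand$start[i]:(cand$start[i] + cand$len[i] - 1L)
    if (!any(taken[span])) { taken[span] <- TRUE; keep[i] <- TRUE }
  }
  out <- cand[keep, ]
  out[order(out$start), ]
}

random_dna <- function(n, probs = c(A = .3, C = .2, G = .2, T = .3)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

# tiny helper: a hairpin string without using the package generator
toy_hairpin <- function(stem, loop) {
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(stem, "")[[1]]),
                                     collapse = ""))
  paste0(stem, loop, rc)
}
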