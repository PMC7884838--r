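#' Homology search configuration
#'
#' Parameters of the internal seed-and-extend nucleotide search. The
#' score scheme defaults to +1/-2 with ungapped Karlin-Altschul
#' parameters lambda = 1.28, K = 0.46, H = 0.85 (standard blastn-like
#' constants for this scheme, stored per scheme in
#' `ka_constants()`).
#'
#' @param word_size exact-match seed length (default 7).
#' @param evalue_threshold maximum reported E-value (default 1e-10).
#' @param match_score,mismatch_score alignment scores (+1 / -2).
#' @param x_drop extension stops once the running score falls `x_drop`
#'   below the best score seen (default 20).
#' @param lambda,kappa,entropy Karlin-Altschul parameters; defaults come
#'   from [ka_constants()] for the chosen score pair.
#' @return object of class `homology_config`.
#' @export
homology_config <- function(word_size = 7L, evalue_threshold = 1e-10,
                            match_score = 1L, mismatch_score = -2L,
                            x_drop = 20L, lambda = NULL, kappa = NULL,
                            entropy = NULL) {
  stopifnot(word_size >= 4, evalue_threshold > 0,
            match_score > 0, mismatch_score < 0)
  kc <- ka_constants(match_score, mismatch_score)
  structure(list(word_size = as.integer(word_size),
                 evalue_threshold = evalue_threshold,
                 match_score = as.integer(match_score),
                 mismatch_score = as.integer(mismatch_score),
                 x_drop = as.integer(x_drop),
                 lambda = lambda %||% kc[["lambda"]],
                 kappa = kappa %||% kc[["kappa"]],
                 entropy = entropy %||% kc[["entropy"]]),
            class = "homology_config")
}

#' Karlin-Altschul constants per score scheme
#'
#' Ungapped (lambda, K, H) for the common blastn match/mismatch pairs.
#'
#' @param match_score,mismatch_score the score pair.
#' @return named numeric vector `lambda`, `kappa`, `entropy`.
#' @export
ka_constants <- function(match_score = 1L, mismatch_score = -2L) {
  key <- sprintf("%d/%d", match_score, mismatch_score)
  tab <- list(
    "1/-2" = c(lambda = 1.28, kappa = 0.46, entropy = 0.85),
    "1/-3" = c(lambda = 1.37, kappa = 0.71, entropy = 1.31),
    "2/-3" = c(lambda = 0.62, kappa = 0.46, entropy = 0.85))
  tab[[key]] %||% c(lambda = 1.28, kappa = 0.46, entropy = 0.85)
}

#' Karlin-Altschul E-value
#'
#' `E = K * m' * n' * exp(-lambda * S)` with the standard length
#' adjustment `l = log(K * m * n) / H`, `m' = max(m - l, 1/K)`,
#' `n' = max(n - l, 1/K)`. Strictly decreasing in the score.
#'
#' @param score raw alignment score.
#' @param query_length,database_length m and n in bases.
#' @param config a [homology_config()].
#' @param adjust apply the length adjustment (default `TRUE`).
#' @return the E-value.
#' @export
ka_evalue <- function(score, query_length, database_length,
                      config = homology_config(), adjust = TRUE) {
  stopifnot(is.finite(score), query_length >= 1, database_length >= 1)
  m <- query_length; n <- database_length
  K <- config$kappa; lam <- config$lambda
  if (adjust) {
    l <- log(K * m * n) / config$entropy
    m <- max(m - l, 1 / K)
    n <- max(n - l, 1 / K)
  }
  K * m * n * exp(-lam * score)
}

#' Bit score
#'
#' @param score raw score.
#' @param config a [homology_config()].
#' @return `(lambda * S - ln K) / ln 2`.
#' @export
ka_bitscore <- function(score, config = homology_config()) {
  (config$lambda * score - log(config$kappa)) / log(2)
}

#' Build the word index over a reference set
#'
#' Exact-match lookup from every `word_size`-mer of the (forward)
#' references to its (subject, offset) occurrences. Queries are later
#' searched on both of their strands against this forward index.
#' References shorter than the word size can never seed a match and are
#' indexed as seedless with a warning. Duplicate reference ids are an
#' error.
#'
#' @param references a named [Biostrings::DNAStringSet] or character
#'   vector.
#' @param config a [homology_config()].
#' @return object of class `word_index`.
#' @export
build_word_index <- function(references, config = homology_config()) {
  refs <- as_dna(references)
  if (!length(refs)) stop("reference set must be non-empty")
  if (is.null(names(refs))) names(refs) <- sprintf("ref_%04d", seq_along(refs))
  ids <- sub("\\s.*$", "", names(refs))
  if (anyDuplicated(ids))
    stop("duplicate reference id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(refs) <- ids
  w <- config$word_size
  short <- Biostrings::width(refs) < w
  if (any(short))
    warning(sum(short), " reference(s) shorter than word size ", w,
            " are seedless and can never match")
  env <- new.env(hash = TRUE, parent = emptyenv())
  seqs <- as.character(refs)
  for (ri in which(!short)) {
    s <- seqs[ri]
    n <- nchar(s)
    words <- substring(s, 1:(n - w + 1), w:n)
    ok <- !grepl("[^ACGT]", words)
    for (pos in which(ok)) {
      e <- get0(words[pos], envir = env)
      env[[words[pos]]] <- rbind(e, c(ri, pos))
    }
  }
  structure(list(index = env, refs = refs, ref_seqs = seqs,
                 config = config),
            class = "word_index")
}

# Ungapped X-drop extension around a seed; returns score and the aligned
# 1-based intervals on query and subject.
extend_seed <- function(q, s, qpos, spos, w, match, mismatch, x_drop) {
  nq <- length(q); ns <- length(s)
  score <- w * match
  # right
  best <- 0; cur <- 0; ext_r <- 0
  i <- qpos + w; j <- spos + w
  while (i <= nq && j <= ns) {
    cur <- cur + if (q[i] == s[j] && q[i] %in% c("A", "C", "G", "T"))
      match else mismatch
    if (cur > best) { best <- cur; ext_r <- i - (qpos + w) + 1L }
    if (best - cur >= x_drop) break
    i <- i + 1L; j <- j + 1L
  }
  score <- score + best
  # left
  best <- 0; cur <- 0; ext_l <- 0
  i <- qpos - 1L; j <- spos - 1L
  while (i >= 1 && j >= 1) {
    cur <- cur + if (q[i] == s[j] && q[i] %in% c("A", "C", "G", "T"))
      match else mismatch
    if (cur > best) { best <- cur; ext_l <- qpos - i }
    if (best - cur >= x_drop) break
    i <- i - 1L; j <- j - 1L
  }
  score <- score + best
  c(score = score, q_start = qpos - ext_l, q_end = qpos + w - 1L + ext_r,
    s_start = spos - ext_l, s_end = spos + w - 1L + ext_r)
}

#' Seed-and-extend homology search
#'
#' Confirms query sequences (typically scanned candidate loci) against a
#' reference set: exact `word_size`-mer seeds are extended ungapped in
#' both directions with X-drop termination; the best alignment per
#' (query, subject) pair is kept, scored under Karlin-Altschul
#' statistics, and matches with `E <= evalue_threshold` are reported
#' sorted by ascending E-value. Both query strands are searched. Queries
#' shorter than the word size simply produce no hits.
#'
#' @param queries a named [Biostrings::DNAStringSet] or character vector.
#' @param references reference set, or a prebuilt [build_word_index()].
#' @param config a [homology_config()] (ignored when `references` is a
#'   prebuilt index).
#' @return data.frame: `query_id`, `subject_id`, `strand`, `score`,
#'   `bit_score`, `e_value`, `q_start`, `q_end`, `s_start`, `s_end`
#'   (1-based inclusive, query coordinates on the forward query).
#' @export
homology_search <- function(queries, references,
                            config = homology_config()) {
  idx <- if (inherits(references, "word_index")) references
         else build_word_index(references, config)
  config <- idx$config
  qs <- as_dna(queries)
  if (is.null(names(qs))) names(qs) <- sprintf("query_%04d", seq_along(qs))
  w <- config$word_size
  db_len <- sum(Biostrings::width(idx$refs))
  ref_chars <- lapply(idx$ref_seqs, function(s) strsplit(s, "")[[1]])
  out <- list()
  for (qi in seq_along(qs)) {
    qlen <- Biostrings::width(qs)[qi]
    if (qlen < w) next
    best <- list()  # key: subject|strand -> best alignment
    for (strand in c("+", "-")) {
      qseq <- if (strand == "+") as.character(qs[[qi]]) else
        revcomp_chr(as.character(qs[[qi]]))
      qc <- strsplit(qseq, "")[[1]]
      words <- substring(qseq, 1:(qlen - w + 1), w:qlen)
      ok <- which(!grepl("[^ACGT]", words))
      seen_diag <- new.env(hash = TRUE, parent = emptyenv())
      for (qpos in ok) {
        occ <- get0(words[qpos], envir = idx$index)
        if (is.null(occ)) next
        for (oi in seq_len(nrow(occ))) {
          ri <- occ[oi, 1]; spos <- occ[oi, 2]
          diag_key <- sprintf("%d|%s|%d", ri, strand, spos - qpos)
          if (!is.null(get0(diag_key, envir = seen_diag))) next
          assign(diag_key, TRUE, envir = seen_diag)
          al <- extend_seed(qc, ref_chars[[ri]], qpos, spos, w,
                            config$match_score, config$mismatch_score,
                            config$x_drop)
          key <- sprintf("%d|%s", ri, strand)
          if (is.null(best[[key]]) || al[["score"]] > best[[key]][["score"]])
            best[[key]] <- al
        }
      }
    }
    for (key in names(best)) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      ri <- as.integer(parts[1]); strand <- parts[2]
      al <- best[[key]]
      ev <- ka_evalue(al[["score"]], qlen, db_len, config)
      if (ev > config$evalue_threshold) next
      qa <- c(al[["q_start"]], al[["q_end"]])
      if (strand == "-") qa <- c(qlen - al[["q_end"]] + 1L,
                                 qlen - al[["q_start"]] + 1L)
      out[[length(out) + 1L]] <- data.frame(
        query_id = names(qs)[qi], subject_id = names(idx$refs)[ri],
        strand = strand, score = al[["score"]],
        bit_score = ka_bitscore(al[["score"]], config), e_value = ev,
        q_start = qa[1], q_end = qa[2],
        s_start = al[["s_start"]], s_end = al[["s_end"]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(query_id = character(0), subject_id = character(0),
                      strand = character(0), score = numeric(0),
                      bit_score = numeric(0), e_value = numeric(0),
                      q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$e_value, res$query_id, res$subject_id), ]
  rownames(res) <- NULL
  res
}

#' Write homology matches as TSV
#'
#' Mirrors a confirmation table: subject id, scan probability (when the
#' query loci carry one), E-value, plus alignment coordinates.
#'
#' @param matches data.frame from [homology_search()].
#' @param path output file.
#' @param probabilities optional named vector of scan probabilities
#'   keyed by query id.
#' @return `path`, invisibly.
#' @export
write_matches_tsv <- function(matches, path, probabilities = NULL) {
  df <- matches
  if (!is.null(probabilities))
    df <- cbind(df[, "query_id", drop = FALSE],
                probability = unname(probabilities[df$query_id]),
                df[, setdiff(names(df), "query_id")])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
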