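#' Plant-like codon usage table
#'
#' Relative frequencies for the 61 sense codons built from standard
#' amino-acid frequencies with A/T-ending codons up-weighted threefold,
#' reproducing the AT-rich third-position bias of plant coding regions
#' (overall GC of sampled coding sequence is about 0.40).
#'
#' @return named numeric vector over the 61 sense codons, summing to 1.
#' @export
plant_codon_usage <- function() {
  aa_freq <- c(
    A = 0.083, R = 0.055, N = 0.045, D = 0.054, C = 0.014, Q = 0.034,
    E = 0.067, G = 0.071, H = 0.023, I = 0.060, L = 0.097, K = 0.064,
    M = 0.024, F = 0.039, P = 0.047, S = 0.066, T = 0.054, W = 0.011,
    Y = 0.029, V = 0.069)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  w <- vapply(sense, function(cd) {
    third_at <- substr(cd, 3, 3) %in% c("A", "T")
    aa_freq[[code[[cd]]]] * (if (third_at) 3 else 1) / sum(code == code[[cd]])
  }, numeric(1))
  w / sum(w)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. A fixed `seed` makes
#' all generator output byte-identical across runs; sub-generators derive
#' child seeds from it by fixed offsets.
#'
#' @param seed integer seed driving all randomness.
#' @param n_positives number of hairpin (positive) training sequences.
#' @param n_negatives number of coding (negative) training sequences.
#' @param hairpin_length_range `(min, max)` hairpin length in nt.
#' @param loop_length_range `(min, max)` hairpin loop length in nt.
#' @param stem_mutation_rate per-base mutation probability applied to the
#'   assembled hairpin, degrading perfect stem complementarity.
#' @param stem_gc GC fraction of hairpin stem/loop bases. Default 0.55
#'   gives hairpins a compositional signature distinct from both the
#'   AT-rich genome background and coding sequence, standing in for the
#'   real compositional distinctness of plant pre-miRNA hairpins.
#' @param coding_length_range `(min, max)` coding-sequence length in nt
#'   (rounded down to whole codons).
#' @param codon_usage named frequency vector over the 61 sense codons.
#' @param n_contigs number of contigs in the synthetic genome.
#' @param contig_length_range `(min, max)` contig length in bp.
#' @param background_gc overall GC fraction targeted by genome background.
#' @param te_fraction fraction (by length) of genome background built from
#'   TE-like codon-structured segments; the remainder is i.i.d. AT-rich
#'   spacer whose GC is solved so the contig-wide GC equals
#'   `background_gc`.
#' @param planted_ssrs list of `c(motif, repeat_count)` pairs (or a
#'   two-column data.frame) planted into the genome.
#' @param planted_hairpins number of hairpins planted into the genome.
#' @param planted_hairpin_stem_range `(min, max)` stem length of planted
#'   hairpins; the default 36-50 nt (with a 4-10 nt loop) guarantees a
#'   planted locus of at least 76 nt, long enough to contain one full
#'   70-nt scan window at the default 7-nt step.
#' @param planted_known_fraction fraction of planted hairpins copied
#'   verbatim from the positive training set produced by
#'   [sim_hairpins()] with this same config (default 0.5). These play
#'   the role of conserved pre-miRNAs present in the genome, so the
#'   homology-confirmation stage has true homologs to find; the
#'   remainder are novel hairpins invisible to homology search. Truth
#'   payloads record the source id (`hp_001|hairpin_0123`) or
#'   `|novel`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_positives = 1000L,
                       n_negatives = 1000L,
                       hairpin_length_range = c(70L, 300L),
                       loop_length_range = c(4L, 10L),
                       stem_mutation_rate = 0.05,
                       stem_gc = 0.55,
                       coding_length_range = c(150L, 300L),
                       codon_usage = plant_codon_usage(),
                       n_contigs = 5L,
                       contig_length_range = c(5e4L, 3e5L),
                       background_gc = 0.387,
                       te_fraction = 0.8,
                       planted_ssrs = list(),
                       planted_hairpins = 0L,
                       planted_hairpin_stem_range = c(36L, 50L),
                       planted_known_fraction = 0.5) {
  cfg <- list(
    seed = as.integer(seed), n_positives = as.integer(n_positives),
    n_negatives = as.integer(n_negatives),
    hairpin_length_range = as.integer(hairpin_length_range),
    loop_length_range = as.integer(loop_length_range),
    stem_mutation_rate = stem_mutation_rate, stem_gc = stem_gc,
    coding_length_range = as.integer(coding_length_range),
    codon_usage = codon_usage,
    n_contigs = as.integer(n_contigs),
    contig_length_range = as.integer(contig_length_range),
    background_gc = background_gc, te_fraction = te_fraction,
    planted_ssrs = planted_ssrs,
    planted_hairpins = as.integer(planted_hairpins),
    planted_hairpin_stem_range = as.integer(planted_hairpin_stem_range),
    planted_known_fraction = planted_known_fraction)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$seed) == 1, is.finite(cfg$seed),
    cfg$background_gc >= 0, cfg$background_gc <= 1,
    cfg$stem_gc >= 0, cfg$stem_gc <= 1,
    cfg$stem_mutation_rate >= 0, cfg$stem_mutation_rate <= 1,
    cfg$te_fraction >= 0, cfg$te_fraction < 1,
    cfg$planted_known_fraction >= 0, cfg$planted_known_fraction <= 1)
  for (fld in c("hairpin_length_range", "loop_length_range",
                "coding_length_range", "contig_length_range",
                "planted_hairpin_stem_range")) {
    r <- cfg[[fld]]
    if (length(r) != 2 || r[1] > r[2] || r[1] < 1)
      stop(sprintf("%s must be (min, max) with 1 <= min <= max", fld))
  }
  if (cfg$hairpin_length_range[1] < 20)
    stop("hairpins must be at least 20 nt")
  if (cfg$hairpin_length_range[1] < cfg$loop_length_range[1] + 2)
    stop("infeasible hairpin length range: stem + loop cannot fit")
  if (abs(sum(cfg$codon_usage) - 1) > 1e-6 || length(cfg$codon_usage) != 61)
    stop("codon_usage must be 61 sense-codon frequencies summing to 1")
  if (any(Biostrings::GENETIC_CODE[names(cfg$codon_usage)] == "*"))
    stop("codon_usage must not contain stop codons")
  invisible(cfg)
}

stem_base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

rand_bases <- function(n, probs) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# One stem + loop + revcomp(stem) hairpin with per-base mutations.
build_hairpin <- function(len, loop_range, probs, mutation_rate) {
  loop <- sample(loop_range[1]:loop_range[2], 1)
  if ((len - loop) %% 2 == 1) loop <- loop + 1
  stem_len <- (len - loop) / 2
  stem <- rand_bases(stem_len, probs)
  hp <- paste0(stem, rand_bases(loop, probs), revcomp_chr(stem))
  if (mutation_rate > 0) {
    x <- strsplit(hp, "")[[1]]
    hit <- which(runif(length(x)) < mutation_rate)
    if (length(hit))
      x[hit] <- sample(c("A", "C", "G", "T"), length(hit), replace = TRUE)
    hp <- paste(x, collapse = "")
  }
  hp
}

#' Generate the positive (hairpin) training set
#'
#' Each record is stem + loop + reverse-complement(stem), then degraded by
#' per-base mutations at `stem_mutation_rate`. Stands in for a reference
#' collection of plant pre-miRNA hairpins.
#'
#' @param config a [sim_config()].
#' @return a named [Biostrings::DNAStringSet] of `n_positives` hairpins.
#' @export
sim_hairpins <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$n_positives >= 1)
  lr <- config$hairpin_length_range
  if (lr[1] < config$loop_length_range[1] + 2)
    stop("infeasible hairpin length range: stem + loop cannot fit")
  probs <- stem_base_probs(config$stem_gc)
  with_seed(config$seed + 101L, {
    lens <- sample(lr[1]:lr[2], config$n_positives, replace = TRUE)
    seqs <- vapply(lens, build_hairpin, character(1),
                   loop_range = config$loop_length_range, probs = probs,
                   mutation_rate = config$stem_mutation_rate)
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sprintf("hairpin_%04d", seq_along(out))
    out
  })
}

sample_codons <- function(n_codons, usage) {
  paste(sample(names(usage), n_codons, replace = TRUE, prob = usage),
        collapse = "")
}

#' Generate the negative (coding) training set
#'
#' Each record is a concatenation of sense codons drawn from
#' `config$codon_usage`; no in-frame stop codon occurs anywhere and the
#' length is a multiple of 3. Stands in for a plant protein-coding
#' negative set.
#'
#' @param config a [sim_config()].
#' @return a named [Biostrings::DNAStringSet] of `n_negatives` sequences.
#' @export
sim_coding <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$n_negatives >= 1)
  cr <- floor(config$coding_length_range / 3)
  with_seed(config$seed + 202L, {
    n_cod <- sample(cr[1]:cr[2], config$n_negatives, replace = TRUE)
    out <- Biostrings::DNAStringSet(
      vapply(n_cod, sample_codons, character(1), usage = config$codon_usage))
    names(out) <- sprintf("coding_%04d", seq_along(out))
    out
  })
}

# Mosaic background: TE-like ORF segments (te_fraction by length, random
# strand) interleaved with i.i.d. spacer whose GC solves the overall target.
build_background <- function(total_len, config) {
  usage <- config$codon_usage
  cds_gc <- sum(usage * vapply(names(usage), function(cd)
    sum(strsplit(cd, "")[[1]] %in% c("G", "C")), numeric(1))) / 3
  tf <- config$te_fraction
  spacer_gc <- (config$background_gc - tf * cds_gc) / (1 - tf)
  if (spacer_gc < 0 || spacer_gc > 1)
    stop("background_gc unreachable with this te_fraction and codon_usage")
  spacer_probs <- stem_base_probs(spacer_gc)
  parts <- character(0)
  te_len <- 0; got <- 0
  while (got < total_len) {
    if (got == 0 || te_len / got < tf) {
      seg <- sample_codons(ceiling(sample(300:2000, 1) / 3), usage)
      if (runif(1) < 0.5) seg <- revcomp_chr(seg)
      te_len <- te_len + nchar(seg)
    } else {
      seg <- rand_bases(sample(100:500, 1), spacer_probs)
    }
    parts <- c(parts, seg)
    got <- got + nchar(seg)
  }
  substr(paste(parts, collapse = ""), 1, total_len)
}

# Reserve a non-overlapping placement (1-based inclusive) or fail.
place_feature <- function(len, contig_len, taken, margin = 2L,
                          max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    if (contig_len - len - margin < margin + 1) break
    st <- sample((margin + 1):(contig_len - len - margin), 1)
    en <- st + len - 1L
    if (!any(taken$start <= en + margin & taken$end >= st - margin))
      return(c(st, en))
  }
  NULL
}

#' Generate a synthetic genome with planted features and a truth table
#'
#' Contigs are a repeat-rich mosaic (TE-like codon-structured segments on
#' random strands plus AT-rich spacer) whose overall GC matches
#' `background_gc`. Requested SSRs and hairpins are inserted at recorded,
#' non-overlapping coordinates. SSR flanks are adjusted so a planted repeat
#' cannot extend into the background, keeping truth coordinates exact.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_genome` with elements `contigs`
#'   (named [Biostrings::DNAStringSet]) and `truth` (data.frame with
#'   `contig_id`, `start`, `end` (0-based half-open), `feature_kind`
#'   (`"hairpin"` or `"ssr"`), `payload`).
#' @export
sim_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$n_contigs >= 1)
  ssrs <- config$planted_ssrs
  if (is.data.frame(ssrs))
    ssrs <- lapply(seq_len(nrow(ssrs)), function(i)
      c(as.character(ssrs[i, 1]), as.character(ssrs[i, 2])))
  with_seed(config$seed + 303L, {
    lens <- sample(config$contig_length_range[1]:config$contig_length_range[2],
                   config$n_contigs, replace = TRUE)
    contigs <- vapply(lens, build_background, character(1), config = config)
    names(contigs) <- sprintf("contig_%03d", seq_len(config$n_contigs))

    truth <- data.frame(contig_id = character(0), start = integer(0),
                        end = integer(0), feature_kind = character(0),
                        payload = character(0), stringsAsFactors = FALSE)
    taken <- lapply(seq_len(config$n_contigs),
                    function(i) data.frame(start = integer(0), end = integer(0)))
    splice <- function(ci, st, en, s) {
      substr(contigs[ci], st, en) <<- s
    }
    pick_contig <- function(len) {
      ok <- which(lens >= len + 10)
      if (!length(ok)) stop("planted features exceed contig capacity")
      sample(rep(ok, 2), 1)  # rep() guards length-1 sample() behaviour
    }

    sr <- config$planted_hairpin_stem_range
    if (config$planted_hairpins > 0) {
      n_known <- round(config$planted_known_fraction * config$planted_hairpins)
      known_pool <- if (n_known > 0) sim_hairpins(config) else NULL
      known_idx <- if (n_known > 0)
        sample(rep(seq_along(known_pool), 2), n_known) else integer(0)
      for (i in seq_len(config$planted_hairpins)) {
        if (i <= n_known) {
          src <- known_idx[i]
          hp <- as.character(known_pool[[src]])
          source_tag <- names(known_pool)[src]
        } else {
          stem <- sample(sr[1]:sr[2], 1)
          loop <- sample(config$loop_length_range[1]:config$loop_length_range[2], 1)
          probs <- stem_base_probs(config$stem_gc)
          s <- rand_bases(stem, probs)
          hp <- paste0(s, rand_bases(loop, probs), revcomp_chr(s))
          if (config$stem_mutation_rate > 0) {
            x <- strsplit(hp, "")[[1]]
            hit <- which(runif(length(x)) < config$stem_mutation_rate)
            if (length(hit))
              x[hit] <- sample(c("A", "C", "G", "T"), length(hit), TRUE)
            hp <- paste(x, collapse = "")
          }
          source_tag <- "novel"
        }
        len <- nchar(hp)
        ci <- pick_contig(len)
        pos <- place_feature(len, lens[ci], taken[[ci]])
        if (is.null(pos)) stop("planted features exceed contig capacity")
        splice(ci, pos[1], pos[2], hp)
        taken[[ci]] <- rbind(taken[[ci]],
                             data.frame(start = pos[1], end = pos[2]))
        truth <- rbind(truth, data.frame(
          contig_id = names(contigs)[ci], start = pos[1] - 1L, end = pos[2],
          feature_kind = "hairpin",
          payload = sprintf("hp_%03d|%s", i, source_tag),
          stringsAsFactors = FALSE))
      }
    }

    if (length(ssrs)) {
      for (i in seq_along(ssrs)) {
        motif <- toupper(ssrs[[i]][1])
        count <- as.integer(ssrs[[i]][2])
        if (!grepl("^[ACGT]{1,6}$", motif))
          stop("planted SSR motifs must be 1-6 nt over ACGT")
        m <- nchar(motif)
        len <- m * count
        ci <- pick_contig(len)
        pos <- place_feature(len, lens[ci], taken[[ci]])
        if (is.null(pos)) stop("planted features exceed contig capacity")
        splice(ci, pos[1], pos[2], strrep(motif, count))
        # break periodicity at both flanks so the plant stays maximal
        last <- substr(motif, m, m); first <- substr(motif, 1, 1)
        splice(ci, pos[1] - 1L, pos[1] - 1L,
               sample(setdiff(c("A", "C", "G", "T"), last), 1))
        splice(ci, pos[2] + 1L, pos[2] + 1L,
               sample(setdiff(c("A", "C", "G", "T"), first), 1))
        taken[[ci]] <- rbind(taken[[ci]],
                             data.frame(start = pos[1] - 1L, end = pos[2] + 1L))
        truth <- rbind(truth, data.frame(
          contig_id = names(contigs)[ci], start = pos[1] - 1L, end = pos[2],
          feature_kind = "ssr",
          payload = sprintf("%s:%d", motif, count), stringsAsFactors = FALSE))
      }
    }

    out <- list(contigs = as_dna(contigs), truth = truth, config = config)
    class(out) <- "sim_genome"
    out
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("Synthetic genome: %d contigs, %s bp total, %d planted features\n",
              length(x$contigs),
              format(sum(Biostrings::width(x$contigs)), big.mark = ","),
              nrow(x$truth)))
  invisible(x)
}

#' Write a truth table as BED
#'
#' Coordinates are 0-based half-open; the name column is
#' `feature_kind|payload`.
#'
#' @param truth the `truth` data.frame from [sim_genome()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  bed <- data.frame(chrom = truth$contig_id, start = truth$start,
                    end = truth$end,
                    name = paste0(truth$feature_kind, "|", truth$payload))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
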