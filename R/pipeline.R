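#' Pipeline configuration
#'
#' Nests the per-stage configurations behind a single seed. Fully
#' serializable to JSON; the effective configuration's hash is embedded
#' in every output header so a run can be traced to its settings.
#'
#' @param seed master seed; every stage derives from it.
#' @param sim a [sim_config()] (its seed is overridden by `seed`).
#' @param scan a [scan_config()].
#' @param homology a [homology_config()].
#' @param ssr an [ssr_config()].
#' @param train_fraction classifier split fraction.
#' @param min_contig_length assembly length filter before scanning.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            scan = scan_config(),
                            homology = homology_config(),
                            ssr = ssr_config(),
                            train_fraction = 0.7,
                            min_contig_length = 500L) {
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), sim = sim, scan = scan,
                 homology = homology, ssr = ssr,
                 train_fraction = train_fraction,
                 min_contig_length = as.integer(min_contig_length)),
            class = "pipeline_config")
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else unclass(x)
}

config_json <- function(config) {
  jsonlite::toJSON(strip_classes(config), auto_unbox = TRUE, digits = NA)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(config_json(config), tmp)
  unname(tools::md5sum(tmp))
}

# header lines for every artifact; the timestamp line is excluded from
# checksums so identical configs give identical manifests.
artifact_header <- function(cfg_hash) {
  c(sprintf("# premirscan %s", as.character(utils::packageVersion("premirscan"))),
    sprintf("# config: %s", cfg_hash),
    sprintf("# timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                      tz = "UTC")))
}

write_with_header <- function(writer, path, cfg_hash) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writer(tmp)
  writeLines(c(artifact_header(cfg_hash), readLines(tmp, warn = FALSE)), path)
  path
}

# md5 over content minus the timestamp line
artifact_checksum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "# timestamp:")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline on synthetic data
#'
#' Executes, in order: simulate (training sets + genome), assembly
#' statistics, featurize, classifier bench, genome scan with the best
#' model, homology confirmation of candidate loci against the hairpin
#' reference set, SSR mining, and the summary report. All artifacts are
#' written under `out_dir` with a provenance header (package version,
#' config hash, UTC timestamp); the returned manifest lists each
#' artifact with a checksum computed over its content minus the
#' timestamp line, so identical config + seed yields identical
#' checksums.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress stage-tagged progress lines on stderr.
#' @return the run manifest (list), invisibly written to
#'   `manifest.json`: config, config hash, per-stage artifact paths and
#'   checksums, and headline numbers (best algorithm, locus and SSR
#'   counts, confirmed matches).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile(),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, msg)
    if (!quiet) message(sprintf("[%s] %s", stage, msg))
  cfg_hash <- config_hash(config)
  artifacts <- character(0)
  add <- function(path) artifacts <<- c(artifacts, path)

  say("simulate", "generating training sets and genome")
  pos <- sim_hairpins(config$sim)
  neg <- sim_coding(config$sim)
  gen <- sim_genome(config$sim)
  write_fasta(pos, file.path(out_dir, "hairpins.fasta")); add(file.path(out_dir, "hairpins.fasta"))
  write_fasta(neg, file.path(out_dir, "coding.fasta")); add(file.path(out_dir, "coding.fasta"))
  write_fasta(gen$contigs, file.path(out_dir, "genome.fasta")); add(file.path(out_dir, "genome.fasta"))
  write_truth_bed(gen$truth, file.path(out_dir, "truth.bed")); add(file.path(out_dir, "truth.bed"))

  say("stats", "assembly statistics")
  contigs <- filter_min_length(gen$contigs, config$min_contig_length)
  st <- assembly_stats(contigs)
  p <- write_with_header(function(tmp) {
    df <- data.frame(statistic = names(unclass(st)),
                     value = unlist(unclass(st)))
    write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  }, file.path(out_dir, "assembly_stats.tsv"), cfg_hash)
  add(p)

  say("featurize", "k-mer featurization (k = 4)")
  m <- kmer_matrix(pos, neg, k = 4)

  say("bench", "training and evaluating the five classifiers")
  bench <- bench_classifiers(m, config$train_fraction, seed = config$seed)
  p <- write_with_header(function(tmp) write_bench_tsv(bench, tmp),
                         file.path(out_dir, "bench_metrics.tsv"), cfg_hash)
  add(p)
  say("bench", sprintf("best algorithm: %s", toupper(bench$best)))

  say("scan", sprintf("scanning %d contig(s) with %s",
                      length(contigs), toupper(bench$best)))
  hits <- scan_genome(contigs, bench$models[[bench$best]], config$scan)
  loci <- merge_hits(hits, config$scan)
  write_loci_bed(loci, file.path(out_dir, "loci.bed")); add(file.path(out_dir, "loci.bed"))
  write_loci_gff3(loci, file.path(out_dir, "loci.gff3")); add(file.path(out_dir, "loci.gff3"))
  say("scan", sprintf("%d hits -> %d candidate loci", nrow(hits), nrow(loci)))

  say("confirm", "homology confirmation against the hairpin reference set")
  matches <- if (nrow(loci)) {
    homology_search(locus_sequences(loci, contigs), pos, config$homology)
  } else {
    homology_search(Biostrings::DNAStringSet(), pos, config$homology)
  }
  probs <- setNames(loci$max_probability, loci$locus_id)
  p <- write_with_header(function(tmp) write_matches_tsv(matches, tmp, probs),
                         file.path(out_dir, "confirmed_matches.tsv"), cfg_hash)
  add(p)

  say("ssr", "microsatellite mining")
  ssrs <- find_ssrs(contigs, config$ssr)
  write_ssr_bed(ssrs, file.path(out_dir, "ssr_loci.bed")); add(file.path(out_dir, "ssr_loci.bed"))

  say("report", "summary report")
  ssum <- ssr_summary(ssrs, st$total_length)
  p <- write_with_header(function(tmp) {
    df <- ssum$per_length
    df <- rbind(df, data.frame(motif_length = "total", n = ssum$total,
                               percent = if (ssum$total) 100 else NA))
    write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf("# density_kb_per_locus\t%s\n",
                format(ssum$density_kb)), file = tmp, append = TRUE)
  }, file.path(out_dir, "ssr_summary.tsv"), cfg_hash)
  add(p)

  manifest <- list(
    premirscan_version = as.character(utils::packageVersion("premirscan")),
    config = jsonlite::fromJSON(config_json(config)),
    config_hash = cfg_hash,
    timestamp_utc = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    artifacts = lapply(setNames(artifacts, basename(artifacts)),
                       artifact_checksum),
    results = list(best_algorithm = bench$best,
                   n_scan_hits = nrow(hits),
                   n_candidate_loci = nrow(loci),
                   n_confirmed_matches = nrow(matches),
                   n_ssr_loci = nrow(ssrs),
                   ssr_density_kb = ssum$density_kb))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
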