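# Oracle model: probability 1 exactly on all-G windows (feature GGGG = 1),
# which also fires on all-C windows via the reverse strand.
g_block_model <- function() {
  oracle_classifier(function(x) as.numeric(x[, "GGGG"] == 1))
}

test_that("window enumeration respects length, step and containment", {
  expect_length(scan_windows(69, scan_config(window_length = 70)), 0)
  expect_equal(scan_windows(70, scan_config(window_length = 70)), 0)
  expect_equal(scan_windows(84, scan_config(window_length = 70, step = 7)),
               c(0, 7, 14))
  expect_equal(scan_windows(100, scan_config(window_length = 10, step = 10)),
               seq(0, 90, 10))
})

test_that("scan finds planted signature blocks and maps strands back", {
  set.seed(21)
  bg <- paste(sample(c("A", "T"), 2000, TRUE), collapse = "")
  # plant an all-G block at 0-based [700, 800)
  contig <- paste0(substr(bg, 1, 700), strrep("G", 100),
                   substr(bg, 801, 2000))
  hits <- scan_genome(c(ctg = contig), g_block_model(),
                      scan_config(probability_threshold = 0.9))
  fwd <- hits[hits$strand == "+", ]
  expect_true(nrow(fwd) >= 1)
  expect_true(all(fwd$start >= 700 & fwd$end <= 800))
  # reverse strand: revcomp windows of the G block are all C -> no GGGG
  expect_equal(nrow(hits[hits$strand == "-", ]), 0)
  # a C block is invisible forward but fires on the reverse strand at
  # mirrored (identical forward-mapped) coordinates
  contig_c <- chartr("G", "C", contig)
  hits_c <- scan_genome(c(ctg = contig_c), g_block_model(),
                        scan_config(probability_threshold = 0.9))
  rev <- hits_c[hits_c$strand == "-", ]
  expect_true(nrow(rev) >= 1)
  expect_true(all(rev$start >= 700 & rev$end <= 800))
  expect_equal(nrow(hits_c[hits_c$strand == "+", ]), 0)
})

test_that("a never-firing model yields zero hits and empty loci", {
  null_model <- oracle_classifier(function(x) rep(0, nrow(x)))
  hits <- scan_genome(c(a = strrep("ACGT", 100)), null_model)
  expect_equal(nrow(hits), 0)
  expect_equal(nrow(merge_hits(hits)), 0)
})

test_that("threshold filtering equals rescanning at the higher threshold", {
  cfg <- sim_config(seed = 33, n_contigs = 1,
                    contig_length_range = c(20000, 20000),
                    planted_hairpins = 3)
  g <- sim_genome(cfg)
  noisy <- oracle_classifier(function(x) pmin(1, x[, "GGGG"] * 20 +
                                                x[, "ATAT"] * 10))
  lo <- scan_genome(g$contigs, noisy,
                    scan_config(probability_threshold = 0.05))
  hi <- scan_genome(g$contigs, noisy,
                    scan_config(probability_threshold = 0.5))
  expect_equal(hi, lo[lo$probability >= 0.5, ], ignore_attr = TRUE)
  expect_lte(nrow(hi), nrow(lo))
})

test_that("model/featurizer k mismatch is caught before scanning", {
  m3 <- oracle_classifier(function(x) rep(1, nrow(x)), k = 3)
  expect_error(scan_genome(c(a = strrep("ACGT", 50)), m3, k = 4),
               "k = 3")
})

test_that("merging collapses overlapping same-strand hits and conserves counts", {
  h <- data.frame(contig_id = "c", start = c(0L, 7L, 200L),
                  end = c(70L, 77L, 270L), strand = "+",
                  probability = c(.96, .99, .97))
  loci <- merge_hits(h)
  expect_equal(nrow(loci), 2)
  expect_equal(loci$start, c(0L, 200L))
  expect_equal(loci$end, c(77L, 270L))
  expect_equal(loci$max_probability, c(.99, .97))
  expect_equal(sum(loci$n_supporting_windows), nrow(h))
  # strand-separated hits never merge
  h2 <- h; h2$strand <- c("+", "-", "+")
  expect_equal(nrow(merge_hits(h2)), 3)
  # merge_gap joins near-abutting hits
  h3 <- data.frame(contig_id = "c", start = c(0L, 75L), end = c(70L, 145L),
                   strand = "+", probability = .99)
  expect_equal(nrow(merge_hits(h3, scan_config(merge_gap = 0))), 2)
  expect_equal(nrow(merge_hits(h3, scan_config(merge_gap = 5))), 1)
})

test_that("merged loci are pairwise non-overlapping per contig and strand", {
  set.seed(12)
  h <- data.frame(contig_id = sample(c("a", "b"), 200, TRUE),
                  start = sample(0:2000, 200, TRUE), strand = "+",
                  probability = runif(200, 0.95, 1))
  h$end <- h$start + 70L
  loci <- merge_hits(h)
  for (cid in unique(loci$contig_id)) {
    l <- loci[loci$contig_id == cid, ]
    l <- l[order(l$start), ]
    if (nrow(l) > 1) expect_true(all(l$start[-1] > l$end[-nrow(l)]))
  }
  expect_equal(sum(loci$n_supporting_windows), 200)
})

test_that("locus sequences and writers round-trip coordinates", {
  contig <- c(ctg = paste0(strrep("A", 50), strrep("G", 30), strrep("T", 20)))
  loci <- data.frame(locus_id = "locus_00001", contig_id = "ctg",
                     start = 50L, end = 80L, strand = "+",
                     max_probability = 0.999, n_supporting_windows = 2L)
  s <- locus_sequences(loci, contig)
  expect_equal(as.character(s[[1]]), strrep("G", 30))
  bed <- tempfile(); gff <- tempfile()
  write_loci_bed(loci, bed)
  write_loci_gff3(loci, gff)
  b <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(b[2:3], c("50", "80"))
  expect_equal(b[5], "999")
  g <- readLines(gff)
  expect_equal(g[1], "##gff-version 3")
  expect_match(g[2], "\t51\t80\t")  # GFF3 is 1-based inclusive
})
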