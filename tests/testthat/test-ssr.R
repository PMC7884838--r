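test_that("threshold rules: mono >= 10 bases, 2-6 nt motifs >= 5 repeats", {
  hit <- find_ssrs(strrep("A", 10))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$motif, "A")
  expect_equal(hit$repeat_count, 10)
  expect_equal(nrow(find_ssrs(strrep("A", 9))), 0)
  di <- find_ssrs(strrep("AT", 5))
  expect_equal(nrow(di), 1)
  expect_equal(di[, c("motif", "repeat_count", "length")],
               data.frame(motif = "AT", repeat_count = 5L, length = 10L))
  expect_equal(nrow(find_ssrs(strrep("AT", 4))), 0)
  tri <- find_ssrs(strrep("ACG", 5))
  expect_equal(tri$motif, "ACG")
  expect_equal(tri$length, 15)
})

test_that("runs are broken at ambiguous bases", {
  expect_equal(nrow(find_ssrs("AAAANAAAA")), 0)
  x <- find_ssrs(paste0(strrep("A", 10), "N", strrep("A", 12)))
  expect_equal(nrow(x), 2)
  expect_equal(x$repeat_count, c(10L, 12L))
})

test_that("motifs are primitive: an A-run is mono, not AA x n", {
  x <- find_ssrs(strrep("A", 20))
  expect_equal(nrow(x), 1)
  expect_equal(x$motif, "A")
  # ATAT...: reported with period 2, never period 4
  x <- find_ssrs(strrep("AT", 8))
  expect_equal(x$motif, "AT")
})

test_that("coordinates are 0-based half-open with exact spans", {
  s <- paste0("GCGC", strrep("CAG", 6), "GGTT")
  x <- find_ssrs(c(chr = s))
  expect_equal(nrow(x), 1)
  expect_equal(x$start, 4L)
  expect_equal(x$end, 4L + 18L)
  expect_equal(substr(s, x$start + 1, x$end), strrep("CAG", 6))
  expect_equal(x$end - x$start, nchar(x$motif) * x$repeat_count)
})

test_that("canonical motif class minimizes over rotations and revcomp", {
  expect_equal(canonical_motif("TA"), "AT")
  expect_equal(canonical_motif("AT"), "AT")
  expect_equal(canonical_motif("GAA"), "AAG")  # min of 6 candidates
  expect_equal(canonical_motif("G"), "C")      # revcomp of G
  expect_equal(canonical_motif(c("TTC", "CTT")), c("AAG", "AAG"))
  expect_error(canonical_motif("AN"), "ACGT")
})

test_that("overlap precedence: longer run wins, then shorter motif, leftmost", {
  # A x 12 followed by (AT) x 5: the A-run (12) beats the AT-run (10)
  # where they touch, but both survive as non-overlapping loci
  s <- paste0(strrep("A", 12), strrep("T", 3), strrep("GA", 6), "C")
  x <- find_ssrs(s)
  expect_equal(x$motif, c("A", "GA"))
  expect_true(all(diff(ord <- order(x$start)) > 0))
  for (i in seq_len(nrow(x) - 1))
    expect_lte(x$end[i], x$start[i + 1])
})

test_that("miner matches the brute-force oracle on random sequences", {
  set.seed(77)
  for (i in 1:25) {
    s <- random_dna(4000)
    # sprinkle ambiguity
    pos <- sample(4000, 5)
    for (p in pos) substr(s, p, p) <- "N"
    got <- find_ssrs(c(seq1 = s))
    want <- oracle_find_ssrs(s)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start - 1L)
    expect_equal(got$motif, want$motif)
    expect_equal(got$repeat_count, want$count)
  }
})

test_that("summary percentages, density and printing conventions", {
  loci <- data.frame(contig_id = "c", start = 0, end = 10,
                     motif = c("A", "A", "AT", "ACG"),
                     repeat_count = c(10L, 12L, 5L, 6L),
                     length = c(10L, 12L, 10L, 18L),
                     motif_class = c("A", "A", "AT", "AAG"))
  sm <- ssr_summary(loci, 8000)
  expect_equal(sm$per_length$n, c(2, 1, 1, 0, 0, 0))
  expect_equal(sm$per_length$percent[1], 50)
  expect_equal(sum(sm$per_length$percent), 100)
  expect_equal(sm$density_kb, 2.0)  # 8 kb / 4 loci
  one <- ssr_summary(loci[1, ], 1000)
  expect_equal(one$density_kb, 1.0)
  expect_equal(one$per_length$percent[1], 100)
  empty <- ssr_summary(loci[0, ], 1000)
  expect_true(is.na(empty$density_kb))
})

test_that("planted SSRs are recovered exactly; sub-threshold plants never", {
  cfg <- sim_config(seed = 41, n_contigs = 3,
                    contig_length_range = c(30000, 60000),
                    planted_ssrs = list(
                      c("A", 10), c("A", 9),        # at / below mono threshold
                      c("AT", 5), c("AT", 4),       # at / below di threshold
                      c("ACG", 7), c("ACGT", 5),
                      c("ACGTC", 5), c("ACGTCA", 5)))
  g <- sim_genome(cfg)
  found <- find_ssrs(g$contigs)
  truth <- g$truth[g$truth$feature_kind == "ssr", ]
  for (i in seq_len(nrow(truth))) {
    parts <- strsplit(truth$payload[i], ":")[[1]]
    motif <- parts[1]; count <- as.integer(parts[2])
    qualifies <- if (nchar(motif) == 1) count >= 10 else count >= 5
    match <- found[found$contig_id == truth$contig_id[i] &
                     found$start == truth$start[i] &
                     found$end == truth$end[i], ]
    if (qualifies) {
      expect_equal(nrow(match), 1, info = truth$payload[i])
      expect_equal(match$motif, motif)
      expect_equal(match$repeat_count, count)
    } else {
      overlap <- found[found$contig_id == truth$contig_id[i] &
                         found$start < truth$end[i] &
                         found$end > truth$start[i], ]
      expect_equal(nrow(overlap), 0, info = truth$payload[i])
    }
  }
})

test_that("reported loci are sorted and non-overlapping per contig", {
  set.seed(55)
  s1 <- random_dna(20000); s2 <- random_dna(20000)
  x <- find_ssrs(c(a = s1, b = s2))
  for (cid in unique(x$contig_id)) {
    l <- x[x$contig_id == cid, ]
    expect_true(!is.unsorted(l$start))
    if (nrow(l) > 1) expect_true(all(l$start[-1] >= l$end[-nrow(l)]))
  }
})
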