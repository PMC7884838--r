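---
title: "Methods: pre-miRNA locus prediction and draft-genome survey statistics"
author: "premirscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre-miRNA locus prediction and draft-genome survey statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the parameters that matter, and the
design decisions taken where more than one defensible choice existed.
It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The problem

Draft plant genome assemblies are routinely surveyed for three things
this package covers: (1) precursor-microRNA (pre-miRNA) coding loci,
found ab initio because RNA-seq-based miRNA discovery misses lowly or
narrowly expressed transcripts; (2) the repetitive fraction —
transposable-element composition and microsatellites; (3) headline
assembly statistics. The pre-miRNA stage is the modelling core: a
pre-miRNA is a ~70–300 nt transcript folding into a stem–loop
(hairpin), and hairpin-coding sequence is separable from protein-coding
sequence in k-mer composition space, which is what the classifiers
exploit.

## k-mer featurization (k = 4)

Each sequence becomes the frequency vector of its 256 tetramers:
sliding windows of width 4 at step 1, windows containing any non-ACGT
symbol discarded, counts divided by the number of retained windows.
Frequencies rather than raw counts make vectors comparable across the
variable sequence lengths the pipeline mixes (70-nt scan windows,
70–300 nt hairpins, 150–300 nt coding sequences); a row sums to
exactly 1 for unambiguous input, and a fully ambiguous sequence maps to
the zero vector and is skipped by the scanner. No strand collapsing is
applied: forward and reverse-complement k-mers are separate features,
and the reverse strand is handled explicitly by the scanner.

## The classifier bench

Five classifiers are trained on hairpin (label 1) versus coding
(label 0) feature rows after a stratified 70/30 split: an RBF-kernel
SVM with Platt probability calibration (`e1071`), a random forest
(300 trees), gradient-boosted trees (`xgboost`, 60 rounds, depth 4,
eta 0.3, single thread for determinism), k-nearest neighbours
(k = 11, odd to avoid vote ties) and Gaussian naive Bayes. Kernel and
hyperparameters are library defaults surfaced through the fitting
function; the recorded seed makes every fit reproducible. Metrics are
precision, accuracy, recall and F-measure from confusion counts at
probability threshold 0.5, plus a trapezoid-rule ROC AUC; zero
denominators yield `NaN` with a warning rather than a silent zero, so
averages cannot be quietly inflated. Model selection maximizes
F-measure, breaking ties by accuracy and then by a fixed order (SVM,
RF, XGBoost, KNN, NB), so selection is deterministic even under exact
metric ties.

## Genome scanning

The selected model scans contigs with a 70-nt window. The step size
defaults to 7 nt (10% of the window) as a sensitivity/runtime
compromise; step 1 gives an exhaustive scan. Both strands are scanned
by default — miRNA hairpins are strand-specific, and the reverse strand
is classified on the reverse complement with coordinates mapped back to
the forward strand. Windows at or above the probability threshold
(default 0.95) become hits; same-strand hits that overlap or abut
within `merge_gap` collapse into candidate loci carrying their maximum
probability and supporting-window count. Raising the threshold can only
remove hits, a monotonicity the tests assert. Windows that lose some
k-mers to ambiguity are still classified from the remaining ones;
windows with no valid k-mer are skipped.

At the default threshold the scan is sensitive, not specific: 70-nt
windows carry only 67 k-mer observations, so composition estimates are
noisy and background windows clear the threshold at an appreciable
rate. This matches the study design the pipeline reproduces, where a
genome-wide scan produced hundreds of candidate loci of which a small
minority survived homology confirmation; specificity is the
confirmation stage's job. The false-locus count on synthetic genomes is
computed and reported by the acceptance script as a regression-tracked
number, not asserted against a target. Users wanting a stricter scan
can raise the threshold (confirmed loci in comparable surveys carry
probabilities above 0.995) or filter loci by
`n_supporting_windows >= 2`.

## Homology confirmation

An internal seed-and-extend nucleotide engine confirms candidate loci
against a reference hairpin set: exact 7-mer seeds (one extension per
diagonal), ungapped bidirectional extension with X-drop 20, match/
mismatch +1/−2, and Karlin–Altschul statistics
`E = K · m' · n' · exp(−λS)` with λ = 1.28, K = 0.46, H = 0.85 for this
score scheme (a constants table keyed by scheme holds the common
alternatives). The standard length adjustment subtracts
`l = ln(K·m·n)/H` from both lengths, flooring at `1/K`. Both query
strands are searched against the forward-indexed references; the best
alignment per (query, subject, strand) is kept and matches at
E ≤ 1e−10 are reported in ascending E order. Gap penalties are not
applied by default because the confirmed alignments this stage exists
for are near-identities; a gapped mode was deliberately left out of
scope. The engine is self-contained — no external BLAST binary — so the
whole pipeline is testable offline; its E-values are engine- and
database-size-dependent and are not comparable digit-for-digit with
other engines.

## SSR mining

Microsatellites are maximal perfect tandem repeats of primitive 1–6 nt
motifs (a motif is primitive when it is not itself a repetition of a
shorter motif — an A-run is reported as mononucleotide, never as
AA × n). Thresholds follow the common survey convention: mononucleotide
runs ≥ 10 bases, 2–6 nt motifs ≥ 5 repeats. Runs break at ambiguous
bases; trailing partial repeats are truncated so locus length equals
motif length × repeat count. When qualifying runs of different periods
overlap, precedence is: longer run, then shorter motif, then leftmost
start, and each genomic position belongs to at most one locus — a
deterministic single-assignment rule chosen because the upstream tools
that popularized these thresholds do not document their overlap
resolution. Each locus also carries a canonical motif class (the
lexicographic minimum over rotations of the motif and its reverse
complement) for motif-distribution plots. Summaries report counts and
percentage shares per motif length (half-up rounding to 2 decimals,
matching printed survey tables) and density as kb of assembly per
locus (1 decimal). Imperfect and compound repeats are out of scope.

## Assembly statistics

N50 is computed on descending contig lengths as the length at which the
cumulative sum first reaches at least half the total; an exact-half tie
is inclusive, the most common convention. The 500-bp minimum-length
filter is boundary-inclusive (`>= 500`), with a flag for the strict
alternative. GC and AT percentages exclude ambiguous bases from the
denominator so they sum to exactly 100 whenever any unambiguous base
exists.

## Composition and coverage arithmetic

The composition module consumes externally produced annotation counts
(e.g. a domain-based TE annotation) and computes shares: per-row
percentages of the grand total and of the class total (2 decimals),
class shares and family-group shares (1 decimal), and catalogue
coverage percentages (1 decimal). Rounding is half-up throughout
because published tables in this field are rounded half-up, and the
bundled quince survey tables reproduce to the printed digit only under
that convention. Rows labelled "Ambiguous" belong to no class: they
count toward the grand total only.

## The synthetic-data generator

The generator is first-class, tested code that defines the conditions
under which the pipeline is exercised.

* **Hairpins** are stem + loop + reverse-complement(stem), lengths
  70–300 nt, loops 4–10 nt, degraded by 5% per-base mutation. Stem and
  loop bases are drawn at GC 0.55: real pre-miRNA hairpin sets differ
  compositionally from both coding sequence and AT-rich plant genome
  background, and this GC contrast is the synthetic stand-in for that
  distinctness. What the generator does **not** emulate is RNA
  secondary-structure thermodynamics: passing benchmarks show the
  pipeline machinery works on compositionally separable classes, not
  that these accuracy levels transfer to real miRBase-versus-CDS data.
* **Coding sequences** are in-frame concatenations of sense codons
  (no stops), 150–300 nt, drawn from a plant-like codon-usage table:
  standard amino-acid frequencies with A/T-ending codons up-weighted
  threefold, giving GC ≈ 0.40 — the AT-rich third-position bias typical
  of plant genes. A uniform-over-61-codons table was rejected because
  it is compositionally almost indistinguishable from uniform random
  sequence in marginal k-mer space, which would make the
  hairpin/coding benchmark unlearnable for marginal-feature classifiers
  and unrepresentative of real, biased coding sequence. A custom table
  is accepted.
* **Genomes** are multi-contig mosaics: TE-like codon-structured
  segments (80% by length, random strand, 300–2000 nt) interleaved with
  i.i.d. AT-rich spacer whose GC is solved so the contig-wide GC equals
  the configured 0.387. The mosaic, rather than a fully i.i.d.
  background, emulates the repeat-rich plant genomes these surveys
  target (retrotransposons, which are degraded coding sequence,
  dominate them); an i.i.d. background is also an out-of-distribution
  input on which calibrated composition classifiers are unreliable, so
  scan benchmarks over it would measure calibration artefacts rather
  than recovery. Planted SSRs get flank bases adjusted to break
  periodicity, so truth-table coordinates are exactly maximal. Planted
  hairpins use stems 36–50 nt (loci 76–110 nt) so at least one full
  70-nt window at step 7 fits inside every planted locus; half of them
  (by default) are verbatim copies drawn from the positive training
  set, playing the role of conserved pre-miRNAs that the homology stage
  can genuinely confirm, while the novel half is invisible to homology
  — reproducing the wide-scan/narrow-confirmation funnel of real
  surveys.
* **Determinism**: one integer seed; sub-generators derive child seeds
  by fixed offsets (+101 hairpins, +202 coding, +303 genome); repeated
  runs are byte-identical, and the caller's RNG state is restored.

## Problem sizes and numerical choices

The shipped benchmark uses 1,000 hairpins vs 1,000 coding sequences
(balanced classes, since the emulated study reports no negative-set
size) with a 70/30 split, and scan recovery is measured on a 1 Mb
four-contig genome with 50 planted hairpins — sizes chosen so the full
suite runs on a single CPU in minutes while keeping binomial noise on
the reported rates small. Frequencies are exact rationals in double
precision; row sums are compared at 1e-9; E-value formula checks at
1e-12 relative error. Degenerate inputs are defined, not accidental:
empty hit lists merge to empty locus tables, zero-locus summaries
report density as undefined, single-class training data and
feature-order mismatches are errors, and metric zero-denominators are
`NaN` with warnings.

## Known limitations

* Composition-only features cap scan specificity at 70 nt; no
  secondary-structure filter (minimum free energy, stem statistics) is
  applied, by design.
* The homology engine is ungapped; diverged homologs needing gapped
  alignment will score lower than a gapped engine would report.
* Published-table reproduction exercises the arithmetic, not the
  upstream annotation: TE counts and TF catalogue sizes are inputs.
* Reproducing the emulated survey's absolute outputs (its locus count,
  its N50) requires its assembly and trained model; those values are
  reference context, not test targets.
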