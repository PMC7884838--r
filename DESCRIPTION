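Package: premirscan
Title: Ab Initio Pre-miRNA Locus Prediction and Draft Genome Survey
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machine-learned ab initio prediction of precursor-microRNA
    (pre-miRNA) coding loci in draft plant genome assemblies, together with
    the survey statistics that accompany a draft-genome report. Sequences are
    parameterized as k-mer (k = 4) frequency vectors; five classifiers
    (support vector machine, random forest, gradient boosting, k-nearest
    neighbours, naive Bayes) are benchmarked with precision, accuracy,
    recall and F-measure; the selected model scans assembly contigs with a
    70-nucleotide sliding window; and candidate loci are confirmed against a
    reference hairpin set by an internal seed-and-extend nucleotide search
    with Karlin-Altschul E-values. Also included: a seeded synthetic-data
    generator (hairpin and codon-structured training sets, repeat-rich
    mosaic genomes with planted features and a truth table), microsatellite
    (SSR) mining under perfect-repeat rules, N50/GC assembly statistics, and
    transposable-element composition and coverage arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    e1071,
    randomForest,
    xgboost,
    class,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    graphics
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
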