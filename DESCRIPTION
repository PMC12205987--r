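Package: siRNAscreen
Title: Design and Analysis of Chemically Modified siRNA Efficacy Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and analysing screens of fully chemically
    modified siRNAs against native and reporter readouts. Implements 20-nt
    target-site enumeration with GC, homopolymer and transcriptome-homology
    filters and three panel-selection strategies (spaced primary panel, walk
    around hits, 3'-UTR selective); plate normalization to percent of
    untreated with Grubbs outlier handling and trichotomous hit
    classification; scaffold-pair permissive/restrictive analysis, hit-rate
    comparisons and hotspot detection; merged-transcript construction from
    isoform annotation, 50-mer consensus windows, poly(A)-site calling from
    3'-end tag data and translation-efficiency estimation; nearest-neighbor
    stacking thermodynamics with positional group comparisons; and a
    random-forest efficacy classifier evaluated by a prevalence-adjusted
    area under the precision-recall curve. A seeded synthetic-data generator
    provides ground-truth genes, panels, screens, 3'-end tags and coverage
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
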