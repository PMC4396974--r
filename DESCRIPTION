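Package: offtargetCN
Title: Genome-Wide Copy Number Profiles from Off-Target Reads of Targeted Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives genome-wide DNA copy-number profiles from the off-target
    reads of targeted sequencing experiments (whole-exome, gene panels,
    ChIP-seq). Reads are quality-filtered, capture-enrichment peaks are
    detected with a local-Poisson caller and masked, depth of coverage is
    computed in fixed-width bins and compensated for the masked territory,
    corrected for GC content and mappability with loess fits, median
    normalized and log2 transformed, optionally expressed relative to a
    matched reference, and segmented with permutation-based circular binary
    segmentation. Includes an exon-level depth-of-coverage comparator,
    evaluation statistics (diff-based MAD, signal-to-noise ratios, weighted
    segment concordance, random-placement overlap simulation, array pseudo
    counts) and a targeted-capture read simulator with known copy-number
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    matrixStats,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
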