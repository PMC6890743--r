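Package: lncmir
Title: Discovery of Seed- and Pod-Development Regulatory lncRNAs and miRNAs
    from Assembled Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested reimplementation of a transcriptome-based pipeline for
    discovering regulatory non-coding RNAs in developing legume seed and pod
    tissues. Starting from assembled transcripts and a stage-wise FPKM table,
    the package identifies long non-coding RNAs through a filter cascade
    (length, expression, ORF, coding potential, exclusion lists) and classifies
    them by genomic locus; predicts miRNAs by homology to known matures with
    thermodynamic hairpin validation (MFEI, AU content, ensemble entropy and
    base-pair distance, base-pairing propensity, miRNA* integrity); links
    ncRNAs to targets (expectation-scored miRNA/UTR scan, 10 kb cis window,
    duplex-energy trans targets) and detects endogenous target mimic sites
    with the central-bulge rule set; and computes the expression-layer
    statistics (log2 fold change, differential-expression filter, Pearson
    correlation of interacting pairs, comparative-Ct relative expression).
    A self-validating synthetic-transcriptome generator with planted ground
    truth makes every stage testable without external data, and an internal
    RNA thermodynamics engine (MFE folding, McCaskill-style partition
    function, intermolecular duplex scoring) backs the structure filters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
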