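Package: m5Ctools
Title: Calling, Classifying and Characterizing mRNA m5C Sites from RNA
    Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the discovery and characterization of
    NSUN6-dependent Type II mRNA 5-methylcytosine (m5C) sites. Provides
    conversion-aware per-cytosine counting and binomial site calling from
    RNA bisulfite sequencing alignments, UCCA/G-rich motif classification
    of sites into Type II and Type I, hairpin structure metaprofiling with
    a Nussinov base-pair maximization folder and bootstrap background
    resampling, expression-correlation inference of the writer enzyme,
    barcoded mutagenesis-reporter quantification, reverse-transcription
    stall scoring for miCLIP-style data, and polysome/translation
    efficiency analyses. A seed-deterministic synthetic-data generator
    emits every input format the pipeline consumes with known ground
    truth, so the full workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
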