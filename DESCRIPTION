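Package: cotkit
Title: Genome Reassociation Kinetics, BAC Library Coverage, and Repeat
    Distribution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing large plant genomes from classical
    renaturation-kinetics (Cot) experiments and large-insert clone libraries.
    Implements the multi-component second-order reassociation model with
    nonlinear least-squares fitting, small-sample-corrected model selection
    and studentized-residual outlier rejection; derives per-component genome
    statistics (observed and pure Cot1/2, mean repetition frequency, kinetic
    complexity against an E. coli calibration standard, two-Cot-decade
    ranges); computes BAC library accounting (nuclear clone counts, genome
    equivalents, Clarke-Carbon locus-representation probability, per-array
    coverage); tests repeat-element distribution among arrayed clones with
    the Holst occupancy (urn) model; scans nucleotide sequences for candidate
    miniature inverted-repeat transposable elements (terminal inverted
    repeats flanked by target-site duplications); and generates synthetic
    datasets (noisy Cot curves, simulated macroarray screens, sequences with
    planted elements) so every stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
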