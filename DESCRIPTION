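Package: phospeaks
Title: Sliding-Window ChIP Enrichment Calling, Peak Comparison and
    Capture Hi-C Insulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale re-implementation of a phospho-CTCF ChIP-seq and
    capture Hi-C analysis pipeline. Provides a negative-binomial
    sliding-window enrichment caller with z-thresholding and window merging,
    a peak-feature comparison suite (interval intersection, per-peak
    coverage, linear R-squared, PWM motif scanning with an exact
    tail-probability threshold, conservation averaging, rank tests, genomic
    feature annotation, metagene profiles, codon-read classification), a
    capture-region contact-matrix insulation and TAD-score procedure, and a
    synthetic-data generator with ground truth so every stage can be
    exercised and benchmarked on a laptop.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
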