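Package: ctds
Title: Candidate-Weighted Target-Decoy False Discovery Rate Estimation for
    Peptide-Spectrum Matches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the false discovery rate (FDR) of peptide-spectrum
    matches from shotgun proteomics database searches. Implements the
    classical target-decoy strategy (TDS), optionally with a rank-5
    correction factor, and a candidate-weighted estimator (cTDS) in which
    every target or decoy hit is weighted by the reciprocal of the
    per-spectrum probability that an incorrect match lands on a target or
    decoy candidate peptide. Includes five protein-level decoy database
    generators (reverse, pseudo-reverse, shuffle, pseudo-shuffle, de
    Bruijn), in-silico tryptic digestion with monoisotopic masses and
    modifications, a precursor-mass candidate index with ppm tolerance
    queries, entrapment false-match-rate analysis, q-value computation,
    and a ground-truth simulator for validating FDR estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
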