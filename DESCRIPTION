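Package: tandemshm
Title: Tandem Substitution Analysis for Somatic Hypermutation in B-Cell
    Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Repertoire", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls single and contiguous nucleotide substitutions in
    immunoglobulin V regions from germline-aligned rearrangement records,
    corrects observed tandem counts for coincidental adjacent single
    nucleotide substitutions with a profile-driven Monte-Carlo null model,
    classifies tandem dinucleotide substitutions as juxtalocations or
    inversions, annotates AID hotspot motifs and amino-acid effects, builds
    COSMIC-style DBS-78 doublet substitution catalogs, and scores positional
    selection pressure via a mutational resistance score with quasi-Poisson
    regression. Includes a synthetic repertoire generator with known ground
    truth so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
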