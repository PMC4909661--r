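Package: alnsweep
Title: Optimal Gap-Penalty and Substitution-Matrix Selection for Multiple Sequence Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores candidate multiple sequence alignments against curated
    reference alignments with the sum-of-pairs score (SPS) and column score
    (CS), sweeps a gap-open-penalty by gap-extension-penalty by
    substitution-matrix grid through a pluggable aligner (a built-in
    affine-gap progressive aligner or any external command-line tool such as
    MAFFT), and selects optimal parameters per benchmark dataset via
    MEAN_SPS / MAX_MEAN_SPS aggregation. Includes a BAliBASE-style synthetic
    benchmark generator with known true alignments for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
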