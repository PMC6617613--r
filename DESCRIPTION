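Package: temap
Title: Single-End and Paired-End Mappability of Transposable Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes genome mappability tracks for single-end and paired-end
    read libraries by exhaustive gapless alignment with a mismatch allowance,
    and aggregates per-position scores into transposable-element (TE) locus and
    subfamily summaries. Two calculation routes are provided (summing exact
    k-mer occurrence counts over all k-mers aligning to a position, and
    counting all placements of the position's own k-mer), together with a
    paired-end fragment simulator, a synthetic-genome generator with planted
    TE subfamilies of varying copy number, divergence and 5'-truncation,
    conservative locus-level aggregation, library comparisons, permutation
    tests for group differences in locus mappability, and consensus-coordinate
    mappability profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
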