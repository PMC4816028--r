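Package: sarmap
Title: Suffix-Array Seed-and-Extend DNA Read Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A single-end DNA read mapper built on an uncompressed suffix
    array with a k-mer prefix lookup table stored in compressed row form.
    Reads are split into uniformly spaced seeds, seed matches are extended
    in both directions under a mismatch budget, extensions are clustered
    into candidate alignment locations (CALs), and the remaining gaps are
    completed with affine-gap Smith-Waterman alignment before emitting SAM.
    Includes a dwgsim-style read simulator with encoded ground truth and an
    evaluator implementing the position (+/- 5 bp) and 80% read-coverage
    correctness rules, so mapping accuracy can be measured end to end on
    synthetic genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    parallel,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
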