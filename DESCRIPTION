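Package: seedalign
Title: Seed-and-Extend Short-Read Alignment with Block-Parallel Banded
    Needleman-Wunsch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seed-and-extend short-read aligner built around a
    constant-length (15 bp) k-mer bucket-hash index of the reference
    genome (H3-family hashing with a primary table and a collision
    table) and a banded semi-global Needleman-Wunsch extension engine.
    The extension stage implements a block-decomposed formulation of the
    banded recurrence in which the band is partitioned into consecutive
    v-shaped blocks; each block reports best-path costs on the three
    band diagonals together with their entry-diagonal labels, and block
    scores are concatenated under min-plus composition.  Includes
    single-end and paired-end pipelines (with windowed Smith-Waterman
    mate rescue), a wgsim-style read simulator with ground truth, and a
    mapping evaluator (sensitivity, precision, recall, F-score).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
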