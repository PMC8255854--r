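Package: msashort
Title: Exact Sum-of-Pairs Multiple Alignment of Very Short Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sum-of-pairs scoring of multiple sequence alignments under
    arbitrary metric score schemes, closed-form optimal costs for length-1
    sequence sets (any metric) and length-2 sets (unit metric), and an exact
    small-instance solver based on dynamic programming over the k-dimensional
    position lattice. Includes a full-enumeration brute-force oracle,
    randomized verification of the closed-form optimality results, and a
    counterexample hunter for metrics under which the gapless (trivial)
    alignment stops being optimal. Sequence sets are read from FASTA or plain
    text; score schemes from symmetric TSV matrices over the alphabet plus the
    gap symbol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
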