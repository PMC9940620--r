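Package: biwfa
Title: Bidirectional Wavefront Alignment in Linear Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact global pairwise sequence alignment under gap-affine
    penalties using the wavefront alignment algorithm (WFA) and its
    bidirectional variant (BiWFA). BiWFA runs wavefronts from both sequence
    ends, detects a score-balanced breakpoint where they meet, and recurses
    on the two halves, producing an optimal alignment in working memory
    proportional to the optimal score rather than to the product of the
    sequence lengths. Includes an independent Gotoh dynamic-programming
    oracle for verification, a seeded generator of mutated sequence pairs,
    seq-pair and FASTA readers, batch alignment with tabular results, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr,
    jsonlite
Config/testthat/edition: 3
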