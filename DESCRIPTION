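Package: pcnv
Title: Positional Correlation Natural Vectors for Alignment-Free Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Alignment-free comparison of DNA sequences via the positional
    correlation natural vector (PCNV), an 18-dimensional descriptor built from
    nucleotide counts, mean occurrence positions, positional variances and the
    six pairwise positional covariances of the four nucleotides. Provides
    Euclidean distance matrices between vectors, a deterministic
    neighbor-joining tree builder with Newick output, leave-one-out
    one-nearest-neighbor genotype classification with per-class sensitivity,
    specificity and accuracy reporting, a reproducible synthetic-sequence
    simulator for end-to-end testing, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
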