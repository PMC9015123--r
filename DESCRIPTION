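Package: msazip
Title: Reference-Based Lossless Compression of Multiple Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lossless compression and decompression of aligned FASTA files.
    Sequences are ranked by a column-profile log-likelihood, similar sequences
    are connected in a sparse directed encodability graph whose edge weights
    are exact bit costs of delta-encoding one row against another, and a
    dummy-rooted minimum spanning arborescence (Chu-Liu/Edmonds) selects an
    optimal set of internal reference sequences and a hierarchical referencing
    order. References and mismatch-run metadata are bit-packed and passed
    through a general-purpose entropy backend (bzip2 by default). Includes a
    seeded synthetic alignment generator and benchmarking utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    generics,
    ggplot2,
    methods,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
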