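Package: enhancertopo
Title: Integrative Enhancer Epigenome and Genome Architecture Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative analysis of regulatory-element chromatin
    state and genome architecture in a knockout-versus-control design:
    chromatin-state classification of bound regulatory elements
    (H3K4me3/H3K4me1/H3K27ac/ATAC overlap rules), temporal enhancer activity
    transitions, replicate-level differential signal testing with
    Benjamini-Hochberg correction, Hi-C contact-domain and loop processing
    (merging, loop-domain classification, observed/expected transforms,
    intradomain contact change, A/B compartment eigenvectors oriented by
    active-mark density), TAD- and loop-constrained enhancer-gene linking
    with concordance statistics, hypergeometric cross-species target overlap,
    and mitotic division-orientation geometry. A synthetic-data module
    generates every pipeline input with known planted structure so each
    analysis stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
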