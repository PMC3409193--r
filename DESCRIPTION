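Package: paralogr
Title: Natural History of Multi-Paralog Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs the natural history of multi-paralog gene families
    from region-annotated multiple sequence alignments: pairwise evolutionary
    distances with composite parameter sharing (TN93-CL), smallest-distance
    ortholog assignment, neighbor-joining trees, sliding-window similarity
    scans, micro-indel extraction and binary parsimony coding, Sawyer-style
    gene-conversion fragment statistics with permutation tests, molecular-clock
    dating of gene duplications from two-fold degenerate sites, and a
    sequence-evolution simulator with duplications, losses, micro-indels and
    gene-conversion tracts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
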