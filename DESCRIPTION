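Package: circscape
Title: Circular RNA Expression Landscapes Across Tissues and Ages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of circular RNA (circRNA) back-splice
    junction data across a multi-tissue, multi-age RNA-seq design:
    repertoire construction with a same-tissue replication filter and
    annotation-based genomic classification, circular-to-linear expression
    relationships, tau tissue-specificity scoring, age-correlated
    expression with a resampling independence test, lineage and
    conservation comparisons, and rank-weighted single-sample pathway
    scores with hypergeometric enrichment. Includes a synthetic-data
    generator with planted tissue-specific and age-dependent effects so
    every stage can be exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    rtracklayer,
    GenomicRanges,
    IRanges,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
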