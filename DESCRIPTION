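Package: ampliconmap
Title: Amplicon Mapping and Driver-Gene Nomination from Array-CGH and
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrative copy-number and transcriptomics toolkit for
    mapping recurrent focal amplifications from array-CGH log2-ratio
    profiles and nominating driver genes within them. Provides per-clone
    copy-number state calling, binned aberration-frequency maps, amplicon
    extraction from tiling-array profiles, minimal-common-region
    (consensus) delineation, gene-content queries, RT-qPCR fold-change
    based driver classification, differential expression signatures,
    exact hypergeometric list-overlap tests, weighted Kolmogorov-Smirnov
    gene-set enrichment with permutation-based FDR, phenotype-correlation
    target recovery, an immunohistochemistry H-score activation
    classifier, and seeded synthetic-cohort generators so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
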