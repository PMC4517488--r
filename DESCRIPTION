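Package: promclass
Title: Promoter Occupancy Classification and Enrichment Analysis for ChIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies ChIP-seq-bound gene promoters into a strong,
    initiation-site-peaked class (group I) and a weaker, downstream-peaked
    class (group II) from TSS-anchored binned tag-count matrices, and
    characterises the classes with interval annotation (enhancers,
    G-quadruplex sites, TATA boxes, clustered transcription-factor binding
    sites), a Poisson local-background peak caller, hypergeometric and
    Welch tests, per-factor group-enrichment scores, expression-quintile
    occupancy correlation, and a two-timepoint fold-change/p-value filter
    for knockdown expression tables. A synthetic-data generator emits a
    miniature genome with full ground truth so every stage of the analysis
    is verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
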