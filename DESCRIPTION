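Package: srftargets
Title: Integrated RNA-Seq, ChIP-Seq and Hi-C Classification of TCF-SRF
    Target Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to partition mitogen-induced genes into ternary complex
    factor (TCF) dependent and independent sets and to classify Direct versus
    Indirect TCF-SRF target genes by integrating gene-level RNA-seq counts
    (total and intronic), pseudo-replicate ChIP-seq peak calls, and 10-kb
    resolution Hi-C contact maps. Implements invariant-gene count
    normalization, a conditional negative-binomial induction test, an
    iterative least-absolute-deviation partition of induction ratios between
    genetic backgrounds, pseudo-replicate peak consensus with differential
    occupancy filtering, distance- and coverage-aware significant-interaction
    calling, A/B compartment assignment by principal component analysis, and
    a synthetic-data generator with planted ground truth for every pipeline
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    generics,
    ggplot2,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
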