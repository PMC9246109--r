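Package: embryoArrest
Title: Transcriptomic Typing of Developmentally Arrested Human IVF Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-embryo RNA-seq of human in vitro
    fertilized (IVF) embryos that arrest before compaction. Starting from a
    feature-by-sample count matrix (genes plus aggregated transposable-element
    types), the package performs depth and GC-content normalization, a
    simplified negative-binomial Wald test for differential expression with
    the 4-fold / q <= 0.01 rule, derivation of major-ZGA and maternal-clearance
    gene sets and per-embryo scoring of maternal-to-zygotic transition (MZT)
    completion, classification of arrested embryos into three arrest types by
    co-correlation clustering with nearest-stage assignment, expression-based
    whole-chromosome aneuploidy calls, gene-set activity scoring (Z-score sums
    and means, metabolic state coordinates, transposable-element expression
    fraction), and preranked gene set enrichment analysis. A synthetic-data
    module simulates staged single-embryo count matrices with planted arrest
    types, aneuploidies and signature effects so that every stage of the
    pipeline can be verified against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse
Config/testthat/edition: 3
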