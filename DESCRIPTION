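Package: stagescreen
Title: Stage-Course Co-Expression Screening of Transcription Factors
    Against Biosynthetic Pathway Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens transcription factors for co-expression with the
    structural genes of metabolic pathways (ascorbate, carotenoid and
    flavonoid biosynthesis) across ordered developmental stages of tomato
    fruit in multiple genotypes. Provides RPKM computation and expression
    filtering, stage-over-stage fold-change tables with
    zero-expression conventions, K-means clustering of temporal log2
    expression profiles, Pearson correlation screening with the exact
    t-test significance threshold, per-regulator counting and candidate
    selection, metabolite-transcript correlation, a planted-truth
    synthetic data generator for recovery benchmarking, and a
    reproducible pipeline runner with a digested run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
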