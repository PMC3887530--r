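Package: mesdrm
Title: Antagonistic Transcriptional Regulation Analysis for C. elegans Germline Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for antagonistic gene regulation by the
    germline histone methyltransferase MES-4 and the DRM transcription
    factor complex in Caenorhabditis elegans germlines. Provides two-group
    differential expression with a moderated t-statistic (empirical-Bayes
    variance shrinkage) and Storey q-value false discovery rate estimation,
    significance-intersection classification of antagonistically regulated
    gene classes (X-up, A-up, A-down), restoration-to-wild-type testing,
    chromosome-wide X expression summaries, expression-category enrichment,
    ChIP peak processing with promoter- and gene-body-binding calls, and a
    synthetic-data generator that plants the statistical structure the
    analysis assumes, with ground truth for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
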