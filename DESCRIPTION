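Package: follicledyn
Title: Stage-Resolved Transcriptome Dynamics and Cell Dialogs in Folliculogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for stage-resolved bulk RNA-seq of developing
    ovarian follicles. Identifies differentially expressed genes between
    adjacent follicle stages and between cell types (oocyte, granulosa,
    cumulus) by a fold-change plus p-value rule, tracks stage-specific and
    inherited DEGs around a pivot stage, clusters short expression time
    series against integer-step model profiles with permutation
    significance, infers and classifies ligand-receptor dialogs within and
    between cell types, flags maternal-effect genes from a preimplantation
    embryo series, classifies imprinted-gene expression status, and
    summarizes promoter CpG methylation. Ships a fully deterministic
    synthetic-data generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust,
    xml2
Config/testthat/edition: 3
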