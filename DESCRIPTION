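Package: cfdnaLN
Title: Cell-Free DNA Fragmentomics and Methylation Scoring for Lupus Nephritis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for characterizing plasma cell-free DNA (cfDNA)
    in lupus nephritis from small sequencing cohorts. Implements fragmentomic
    statistics (electropherogram-based fragmentation index, 5' end-motif
    frequencies, GC-corrected short/long fragment ratio), methylation panel
    design (differentially methylated position selection with a moderated
    t-test, 250 bp merging into regions, methylation-correlated block
    construction), region-level methylation metrics (mean beta, methylated
    fragment ratio), a baseline-referenced weighted Fisher methylation score,
    exact small-sample rank-sum tests by full enumeration, and leave-one-out
    cross-validated classification. A synthetic-data module generates all
    pipeline inputs with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rpart,
    randomForest,
    e1071,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
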