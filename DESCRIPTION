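Package: stagewise
Title: Stage-Specific Differential Expression Analysis for Cancer Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting bulk transcriptomes of staged cancers into
    stage-specific signals. Implements per-gene linear models of log2
    expression over controls and four AJCC stages, empirical-Bayes moderated
    t- and F-statistics, stage-versus-control and inter-stage contrast
    matrices, a four-bit stage-string classification with argmax-|lfc| stage
    assignment, a four-pronged significance cascade, a strict
    monotonic-expression screen over ordered stages, and a synthetic-data
    generator with planted ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    generics
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
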