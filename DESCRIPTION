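Package: permeth
Title: Permutation Inference for Capture-Based Differential DNA Methylation and Small RNA Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects differential DNA methylation from methyl-CpG binding
    domain capture sequencing (MBDCap-seq) regional intensities using an
    offset fold-change statistic, correlation-based segmentation of CpG
    sites into methylation units, and length-stratified one-sided
    permutation tests with iterative events-exclusive re-estimation of the
    null distribution. Also provides TPM normalization and permutation-based
    differential-expression testing for small RNA count tables, and a
    synthetic-data generator with recorded ground truth for calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    stats,
    yaml,
    generics,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
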