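Package: mirreg
Title: Integrated miRNA-mRNA Regulation Analysis for Paired Tumor-Normal Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for integrated analysis of paired tumor/normal miRNA and
    mRNA expression profiles: detection filtering, log2 median-centering,
    a consistent-direction differential expression filter, a SAM-style paired
    statistic with sign-flip permutation FDR, a per-miRNA regulation-value
    statistic with correlated/anti-correlated/others gene classification,
    target-prediction set intersection, promoter CpG-density classification
    (HCG/ICG/LCG), hypergeometric GO enrichment with Benjamini-Hochberg
    adjustment, delta-delta-Ct qPCR analysis, and a synthetic-data generator
    that plants known regulatory structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
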