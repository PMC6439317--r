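Package: feconet
Title: Multi-Tissue Co-Expression Networks for Feed Efficiency Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contrasting high- and low-feed-efficiency animals with
    multi-tissue RNA-seq: residual feed intake phenotyping, mixed-model
    (REML) normalization of log2 expression with normalized mean expression
    (NME) summaries, binned standard-deviation differential-expression calls,
    NME-based tissue-specificity calls, regulatory impact factor (RIF)
    scoring of candidate regulators, PCIT partial-correlation filtering of
    co-expression networks, differential connectivity between
    condition-specific networks, hypergeometric gene-set enrichment and
    genomic region-overlap permutation tests. A synthetic-data generator
    emulating the study design (five tissues, two divergent feed-efficiency
    groups, per-library effects, planted differential, tissue-specific and
    regulator-driven structure) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    IRanges,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
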