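Package: cellfidelity
Title: Purity-Aware Transcriptomic Fidelity Scoring of Cancer Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Scores cancer cell lines as transcriptomic models of primary
    tumors while correcting for tumor purity. Provides upper-quartile and
    quantile normalization, parametric empirical-Bayes batch correction,
    purity-correlated gene filtering and regression-based purity adjustment,
    Spearman fidelity correlation matrices and summaries, precision-weighted
    moderated-t differential expression, classic preranked gene set
    enrichment, a modified nearest-template-prediction subtype classifier
    with resampling significance, and representative cell-line panel
    construction. A synthetic cohort generator with known ground truth
    (purity, subtype, batch, contaminating signatures) makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    limma,
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
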