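Package: p300bsbl
Title: Block-Sparse Bayesian Channel Selection for P300 Spellers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Channel selection for P300 event-related-potential
    brain-computer interfaces by block-sparse Bayesian learning (BSBL)
    with regional smoothing. Each EEG channel's time samples form one
    block of the regression weight vector; an EM algorithm estimates a
    per-channel relevance scale, an AR(1) Toeplitz intra-block
    correlation matrix shared across spatial electrode regions, and the
    noise variance, pruning irrelevant channels as it iterates. The
    package also provides a Bayesian linear discriminant classifier, a
    6x6 row/column speller decoding pipeline, spatial region-map
    utilities for 10-20 montages, and synthetic-data generators with
    planted ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
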