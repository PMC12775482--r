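Package: cleavekit
Title: Design and Analysis of Protease Substrates from High-Throughput Cleavage Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for protease substrate design from panel-wide
    cleavage screens. Provides multi-task sequence-to-cleavage-score regression
    with ensemble uncertainty (transformer encoder and bidirectional LSTM
    backbones implemented natively), a conditional autoregressive peptide
    generator steered by panel cleavage-profile tags, a scoring calculus for
    substrate selectivity and screen-calibrated corrected efficiency and
    selectivity, uncertainty-aware substrate nomination with k-mer diversity
    filtering and site-independent baselines, sequence analytics (IceLogo
    matrices, position-wise Kullback-Leibler divergence, k-mer censuses,
    biophysical properties, activity-profile clustering), and a synthetic
    protease-panel simulator so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    pROC,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
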