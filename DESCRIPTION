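Package: sigreverse
Title: Signature-Reversal Drug Repurposing for Diffuse Intrinsic Pontine Glioma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested implementation of a connectivity-map style
    signature-reversal drug-repurposing pipeline for diffuse intrinsic
    pontine glioma (DIPG). Includes an autoencoder embedding for selecting
    surrogate normal controls from a healthy-tissue expression compendium,
    disease-signature construction from bulk RNA-seq (remove-unwanted-variation
    adjustment plus negative-binomial differential expression) and from
    single-cell data, bidirectional Kolmogorov-Smirnov reversal scoring
    (RGES and summarized sRGES) against a drug-perturbation profile library,
    and evaluation of predictions against drug-sensitivity (AC50) data.
    A synthetic-data generator emulates the statistical structure of every
    input so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    edgeR,
    limma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
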