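Package: trispectrakan
Title: Lung Sound Classification with Tri-Spectral Feature Fusion and
    Kolmogorov-Arnold Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for multi-class classification of
    respiratory diseases from auscultation recordings. Reads lung-sound
    corpora in the ICBHI-2017 on-disk layout (PCM wav recordings with
    per-cycle annotation files and a patient diagnosis table), standardizes
    respiratory cycles into fixed-length 6-second segments at 22,050 Hz,
    computes three spectral representations per segment (20-coefficient
    MFCCs, 12-bin chromagrams, 128-band mel spectrograms), and fuses them
    through three convolutional heads into a Kolmogorov-Arnold network
    (KAN) classifier whose edge activations are learnable cubic B-splines.
    Includes a dense-stack hybrid-CNN baseline, a stratified fivefold
    training and evaluation protocol with Nadam optimization, the standard
    one-vs-rest classification metrics, and a seeded generator of annotated
    synthetic lung-sound corpora so the full pipeline is testable without
    any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    generics,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
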