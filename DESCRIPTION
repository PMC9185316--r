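Package: cpsound
Title: Cardiopulmonary Sound Classification with PCA-Residual Features and
    Ensemble Voting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying heart and lung auscultation recordings as
    normal or abnormal. A recording is cut into overlapping fixed-length
    frames, the dominant periodic (heartbeat or breath) structure of each
    frame is removed by principal component analysis and the residual signal
    is summarised by a 27-dimensional feature vector (11 order/shape
    statistics, 13 Mel-frequency cepstral values, 3 power-spectrum
    summaries). Frame-level ensemble classifiers (bagging, AdaBoost,
    GentleBoost, LogitBoost, RUSBoost) are aggregated to sample-level
    decisions by threshold voting, and evaluated by stratified k-fold
    experiments over a threshold sweep. Includes a seeded synthetic
    heart/lung sound simulator with two-channel noise mixtures, WAV input
    and output, digital band filters, and FFT-based noise-reduction
    reporting in decibels.
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
    lhs,
    purrr,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
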