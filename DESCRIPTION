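Package: eegmci
Title: EEG Feature Engineering and Classifier Evaluation for Mild Cognitive Impairment Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Toolkit for resting-state EEG biomarker pipelines targeting mild
    cognitive impairment (MCI) versus healthy-control discrimination. Provides
    band-pass filtering and fixed-window segmentation of 19-channel 10-20
    montage recordings; Welch band powers and interhemispheric asymmetry;
    synchronization-likelihood functional connectivity; eight nonlinear
    descriptors (detrended fluctuation analysis, Higuchi fractal dimension,
    correlation dimension, largest Lyapunov exponent, C0-complexity,
    correlation (K2) entropy, Shannon entropy, approximate entropy);
    sequential backward floating feature selection wrapped around linear
    discriminant analysis; eight classifier families evaluated under
    stratified 10-fold and leave-one-participant-out cross-validation; and a
    seeded synthetic EEG cohort generator so the whole pipeline is testable
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    MASS,
    e1071,
    class,
    rpart,
    stats,
    utils,
    withr,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
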