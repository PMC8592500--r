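Package: spectrogan
Title: Adversarial Synthesis of EEG Spectrograms for Seizure Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying whether synthetic electroencephalography
    (EEG) data can stand in for scarce real recordings in epileptic seizure
    prediction. Simulates EEG-like multichannel signals with class-dependent
    band power (pre-ictal vs interictal), converts them to normalized
    spectrogram images by short-time Fourier transform, trains a deep
    convolutional generative adversarial network (DCGAN) to synthesize
    pre-ictal samples, screens generated samples with a one-class support
    vector machine, and evaluates a convolutional seizure predictor under
    the TRTR/TSTR/TRTS/TSTS train/test regime matrix. Includes event-level
    alarm scoring with a seizure prediction horizon and occurrence period,
    false-prediction rates per hour, a binomial chance-level predictor test,
    and Hanley-McNeil comparison of areas under the ROC curve.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    e1071,
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
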