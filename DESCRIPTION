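Package: uegsim
Title: Forward Modelling and Validation of Unipolar Electrograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward model of the unipolar electrogram (UEG) built from
    stylized action potentials (products of two logistic functions) and a
    position-independent remote component equal to the mean action
    potential, with the UEG obtained as a rescaled difference of the two.
    Includes derivative-based activation and repolarization markers (Wyatt
    method), activation-recovery intervals, beat-stability and spectral
    signal-to-noise quality control with signal averaging, morphology
    correlation and QRS/T-wave area metrics, a grid search over the
    logistic steepness parameters, and a synthetic epicardial-sock data
    generator so the whole analysis pipeline can be exercised end to end
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    pracma,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
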