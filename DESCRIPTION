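Package: sheetflow
Title: Particle Image Velocimetry Quantification of Collective Cell Sheet
    Migration in Scratch-Wound Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies collective cell migration in scratch-wound (wound
    healing) time-lapse movies. Provides a multi-pass FFT cross-correlation
    particle image velocimetry (PIV) engine with subpixel peak fitting and
    normalized-median-test validation, wound-centric migration summaries
    (signed closure velocity, summation maps, displacement and speed
    distributions, automated wound-area closure curves), velocity and strain
    kymographs with chunk-sum feature extraction and PCA phenotype
    clustering, and a seed-deterministic synthetic movie generator with
    exact ground-truth velocity fields for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
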