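Package: ampulla
Title: Ampulla Detection and Cannulation-Difficulty Assessment for ERCP Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for localizing the ampulla of Vater (AOV) in endoscopic
    retrograde cholangiopancreatography (ERCP) images and for grading the expected
    difficulty of selective biliary cannulation. Bounding-box annotations are encoded
    as bivariate-Gaussian soft masks, a compact encoder-decoder convolutional network
    is trained against them with binary cross-entropy, and predicted masks are decoded
    back to boxes by a peak-threshold rule. Detections are scored with intersection-
    over-union, area precision/recall, relative centroid distance and success plots;
    procedural outcomes (cannulation time, additional techniques, failure) map to
    binary and four-class difficulty labels for classifier training under stratified
    fivefold cross-validation. A seeded synthetic-image generator provides
    endoscopy-like fixtures so the whole pipeline is exercisable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
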