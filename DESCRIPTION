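Package: TumorLoc
Title: Tumor Location Features and Survival Prediction for Glioblastoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts tumor location features (maximal-diameter axial slice,
    tumor diameter, and longitudinal/transverse offsets of the tumor center
    from the brain center) from labeled 3D segmentation volumes, reduces
    wide radiomic-style feature tables through a standardization,
    correlation-pruning, variance-inflation-factor, principal-component and
    Benjamini-Hochberg cascade, and evaluates univariate regressors and
    multivariate classifiers of overall survival stratified by resection
    status. Ships a synthetic-data generator producing labeled tumor
    phantoms, correlated feature tables and survival cohorts with known
    ground truth so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml,
    randomForest,
    e1071,
    nnet,
    class
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
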