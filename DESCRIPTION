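Package: lungmorph
Title: Automated Histomorphometry of Airspace Enlargement in Lung Sections
Version: 0.1.0
Authors@R:
    person("Lungmorph", "Developers", email = "lungmorph@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying emphysematous airspace enlargement in
    H&E-stained lung tissue sections. Segments bona-fide airspaces from RGB
    section rasters (green-channel extraction, maximum-deviation unimodal
    thresholding, connected-component labeling, thick-wall erosion and
    convex-hull based exclusion of vessels and bronchioles) and computes the
    morphometric descriptors Lm (mean linear intercept) and the weighted
    mean equivalent-diameter family D0, D1, D2. Also provides micro-CT
    density descriptors (mean lung voxel intensity and relative volume below
    -900 HU) from a calibrated volume and lung mask, nonparametric group
    statistics (median/IQR, Mann-Whitney U), an RBF-kernel SVM
    classifier-evaluation harness with grid search, ROC/AUC and f1 scoring,
    a parallel batch-processing queue with a command-line interface, and a
    synthetic-scene generator with exact ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    parallel,
    png,
    quadprog,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
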