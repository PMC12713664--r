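Package: splash
Title: Parcel-Localized Spline Regression for Task fMRI Activation Mapping
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Spatially adaptive activation modeling for task-based fMRI.
    Within predefined brain parcels, activation coefficients from the
    hemodynamic general linear model are represented on low-rank thin-plate
    regression spline bases and estimated by structured ordinary or feasible
    generalized least squares with AR(p) temporal noise, the spatial basis
    dimension being selected by BIC. Group-level activation is assessed by a
    two-stage hierarchical procedure with selective false discovery rate
    control at the parcel and vertex levels. Includes Gaussian kernel
    smoothing comparators with closed-form bias and variance-attenuation
    oracles, a synthetic spherical-surface simulation harness, and plain-text
    readers and writers for coordinates, parcel labels, stimulus timing and
    dense time-series arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    splines,
    Matrix,
    methods,
    data.table,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC,
    RNifti,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
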