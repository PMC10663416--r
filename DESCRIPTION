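Package: aifcount
Title: Count-Based Regression Modelling of PET Arterial Input Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models raw blood and plasma radioactivity counts from positron
    emission tomography (PET) examinations using Poisson and
    negative-binomial regression with exposure offsets, instead of fitting
    Gaussian models to pre-corrected concentrations.  Provides the full
    arterial-input-function (AIF) workflow: per-sample offset assembly
    (counting duration, sample volume, gamma-counter volume calibration,
    radioactive decay, external dispersion of the automatic blood sampling
    system, blood-to-plasma ratio, and plasma parent fraction), a penalized
    iteratively reweighted least squares engine with restricted maximum
    likelihood smoothing-parameter selection, tri-exponential nonlinear
    Poisson regression initialized by curve stripping, shape-constrained and
    thin-plate spline generalized additive models, hierarchical multi-
    examination models with factor-smooth deviations, randomized quantile
    residual diagnostics, and a synthetic examination generator with known
    ground truth for validation and missing-data experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
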