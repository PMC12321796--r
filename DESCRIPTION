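Package: neoba
Title: Neural Oscillation-Based Brain Age Modelling from EEG Power Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts brain age from resting-state EEG cross-/power-spectra.
    Decomposes each channel's log power spectrum into an aperiodic power-law
    component and Gaussian oscillatory peaks, derives 13 electrode-wise
    oscillatory features (aperiodic offset/exponent, dominant-peak parameters,
    band power ratios, relative band powers), builds per-subject inter-feature
    dependency matrices by correlation-weighted sparse group lasso, and
    regresses age with a small fully connected network trained by
    Levenberg-Marquardt under 10-fold cross-validation.  Predictions are
    explained by layerwise relevance propagation, cohorts are screened for
    outliers by robust Mahalanobis distance per age group, and lifespan
    quantile trajectories of each feature are fitted by penalized spline
    quantile regression.  A seeded synthetic-cohort generator makes the whole
    pipeline testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    splines,
    e1071,
    randomForest,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
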