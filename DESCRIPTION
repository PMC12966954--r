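Package: rvo
Title: Range and Occurrence Distributions for Animal Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous-time movement models (IID, Brownian motion,
    Ornstein-Uhlenbeck, integrated Ornstein-Uhlenbeck, and
    Ornstein-Uhlenbeck foraging processes) for animal telemetry data,
    with exact simulation, Kalman-filter maximum likelihood and AICc
    model selection, variogram diagnostics, and estimators of the two
    distinct utilization distributions that movement processes admit:
    the range distribution (long-run marginal space use, estimated by
    autocorrelated Gaussian density estimation, AKDE, conventional KDE
    and minimum convex polygons) and the occurrence distribution
    (time-averaged conditional path uncertainty, estimated by
    time-series Kriging, with the Brownian bridge movement model as a
    special case). Includes half-sample and within-period holdout
    cross-validation protocols for calibrating coverage areas, and
    seeded simulation experiments on the sampling-rate and
    sampling-duration dependence of both estimator families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
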