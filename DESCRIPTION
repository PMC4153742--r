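Package: bmelur
Title: Spatiotemporal Ozone Exposure Modelling with Kriging, Land-Use
    Regression and Bayesian Maximum Entropy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating daily summer ground-level ozone over a
    sparse monitoring network with three spatiotemporal models: a
    linear-spline mixed-effects land-use regression (LUR), space-time
    simple kriging on hard monitoring data, and a Bayesian Maximum
    Entropy estimator (BME-LUR) that fuses hard data with Gaussian soft
    data derived from the LUR.  Includes Gaussian-kernel spatiotemporal
    detrending with normal-score transformation, a two-component nested
    space-time covariance model (empirical estimation and weighted
    least-squares fitting), leave-one-station-out cross-validation with
    a one-year temporal exclusion, agreement metrics (R-squared, RMSE,
    percent change in mean-square error, Cohen's kappa on air-quality
    standard exceedances), and a synthetic-data generator emulating the
    Quebec ozone monitoring network so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
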