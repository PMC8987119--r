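Package: vbcmr
Title: Integrated von Bertalanffy Growth and Robust-Design
    Capture-Mark-Recapture Models with Spline Size Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits a hierarchical von Bertalanffy growth model to
    capture-recapture length data and embeds it in a three-state
    (available, temporarily unavailable, dead or permanently emigrated)
    robust-design Cormack-Jolly-Seber model, so that individual body size
    can be imputed with uncertainty and used as a covariate of survival,
    daily capture probability, and availability for capture.  Size effects
    on survival and capture probability are penalized low-rank
    truncated-power splines; availability gets a linear size effect.
    Includes a synthetic-data generator that simulates individuals,
    growth, latent states, surveys and detections from the same model
    equations, posterior predictive checks (residual sum of squares for
    growth, Freeman-Tukey for recaptures), split-chain convergence
    diagnostics, and derived quantities such as the annualized recapture
    probability and size-at-age trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
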