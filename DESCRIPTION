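Package: raes
Title: Risk-Adjusted EWMA Control Charts for Survival Monitoring and
    Predictive Biomarker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-phase risk-adjusted survival monitoring for clinical
    trial arms. Phase I fits a Cox proportional hazards model (Efron or
    Breslow ties, Breslow baseline cumulative hazard) to a reference
    (control) arm; Phase II monitors test-arm patients case by case with
    an exponentially weighted moving average (EWMA) control chart of
    standardized martingale-residual scores, with control limits
    calibrated by Monte Carlo to a target per-case false-alarm rate.
    Companion tools identify predictive biomarkers via maximally
    selected log-rank cut-points, treatment-by-biomarker interaction
    Cox models, bootstrap stability assessment, and subgroup-level
    chart monitoring, and a synthetic trial-cohort generator with known
    ground truth exercises every stage at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
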