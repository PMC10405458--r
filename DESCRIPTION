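Package: nirgait
Title: Fitting Continuous Gait Parameters from Cerebral Blood-Oxygen Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits continuous gait parameters (walking-speed and stride-length
    staircases) from multichannel fNIRS hemoglobin time series. Implements
    five-band hemodynamic decomposition with zero-phase Chebyshev filters,
    per-gait-cycle staircase targets from knee inertial traces, a structured
    time/spatial-domain feature battery, hybrid filter/embedded feature
    selection combining absolute Pearson correlation with gradient-boosting
    importance through a harmonic-mean score, autoencoder dimensionality
    reduction, an LSTM sequence regressor with subject-wise cross-validation,
    and R-squared-gated incremental adaptation to new individuals. Ships a
    seeded generator of coupled synthetic fNIRS/gait cohorts so the entire
    pipeline is testable without access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
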