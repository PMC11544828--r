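Package: scgvo2
Title: Seismocardiography-Based Non-Exercise Estimation of Maximal Oxygen Uptake
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and validation toolkit for estimating maximal oxygen
    uptake (VO2max) from resting seismocardiography (SCG). Provides a
    synthetic-data module (subject cohorts, 42-s tri-state SCG recordings,
    breath-by-breath ramp-protocol cardiopulmonary exercise tests), SCG signal
    processing (beat detection, ensemble-average heartbeat, PCA-based waveform
    features), a linear SCG regression model plus published non-exercise
    benchmark equations (FRIENDS, ACSM, Tanaka), the full method-comparison
    statistics suite (bias, MAPE, SEE, Pearson with Fisher intervals,
    Bland-Altman limits of agreement, two-way absolute-agreement ICC, Steiger
    test for dependent correlations, RMS difference, subgroup stratification),
    and an end-to-end reproducible study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
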