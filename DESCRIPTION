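Package: hemobia
Title: Bioimpedance and Hemodynamic Analysis of Hemorrhage-Resuscitation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing segmental multifrequency bioelectrical
    impedance (BIA) and hemodynamic monitoring data from controlled
    hemorrhage and fluid-resuscitation experiments. Includes a
    three-pool (plasma, interstitial, intracellular) fluid-kinetics
    simulator with Cole-model impedance mapping and a volume-driven
    hemodynamic model for generating synthetic swine datasets; an
    impedance-processing chain (z-score standardization, group
    median/percentile curves with B-spline smoothing, the
    impedance/impedance-ratio trajectory, curvature classification, and
    high-frequency-impedance recovery-time detection); and an endpoint
    statistics layer (Jarque-Bera normality, pointwise t-tests, percent
    changes, and a stroke-volume fluid-responsiveness rule).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
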