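Package: nirsync
Title: Interbrain Synchrony Analysis for fNIRS Hyperscanning Dyads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of dyadic fNIRS hyperscanning studies of
    interbrain synchrony (IBS). Provides a synthetic-data generator for coupled
    two-person hemodynamic recordings with physiological noise and motion
    artifacts; optical-density preprocessing (motion detection, spline and
    wavelet correction, PCA-based systemic-noise removal, modified Beer-Lambert
    conversion, cardiac-peak channel quality control, ROI averaging);
    wavelet-transform-coherence quantification of IBS with cone-of-influence
    exclusion; IBS features (level, slope, percent determinism from recurrence
    quantification analysis); permuted-dyad null pairings; communication and
    path-accuracy behavioral features; and linear mixed-effects model
    comparisons for control analyses, manipulation checks, disruption tests and
    moderation analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    yaml,
    data.table
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
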