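Package: fisrisk
Title: Mamdani Fuzzy Inference for Oxidative-Stress-Based Oral Cancer Risk Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-criteria fuzzy decision-support system that scores the
    oxidative-stress-related malignization risk of oral potentially malignant
    disorders from two serum biomarkers: malondialdehyde (MDA, nmol/ml) and
    proton-donor capacity (inhibition percent). Provides triangular and
    trapezoidal membership-function primitives, five-term linguistic
    partitions, a generic Mamdani engine (MIN firing, MIN-clip implication,
    MAX aggregation, centroid defuzzification) with full inference traces,
    the 25-rule oral-cancer rule base, a calibration stage that recovers
    membership-knot geometry from a published input/output table by
    derivative-free least squares, batch patient scoring, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
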