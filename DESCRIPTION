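Package: cogdisp
Title: Intraindividual Cognitive Dispersion Analysis for Prodromal
    Synucleinopathy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying intraindividual cognitive variability
    (dispersion) in prodromal neuronal alpha-synuclein disease cohorts.
    Implements regression-based internal normative T-scoring of an
    11-test neuropsychological battery, coefficient-of-variation
    dispersion metrics (total and attention/executive), NSD-ISS stage
    assignment with one-year conversion labeling, two-group comparison
    statistics with variance-gated test selection, Cohen's d and
    Benjamini-Hochberg false-discovery-rate control, and binomial
    logistic conversion-prediction models fit by iteratively reweighted
    least squares with Nagelkerke R-squared and Hosmer-Lemeshow
    calibration statistics. A seeded synthetic cohort generator with a
    deterministic quadrature-based calibration layer emulates the
    statistical structure such analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
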