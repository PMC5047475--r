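Package: cystindex
Title: Biomarker-Based Estimation of Renal Cystic Index in an ARPKD Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives an empirical calculator for renal cystic index (CI, the
    percent of kidney cross-section occupied by cysts) from blood and urine
    biomarkers measured in the PCK rat model of autosomal recessive polycystic
    kidney disease. Screens each candidate biomarker against histological CI
    with four trendline families (linear, exponential, logarithmic, quadratic),
    applies a correlation gate (r >= 0.7, p < 0.05) with a linear-preference
    rule, and combines the surviving univariate linear equations by equal-weight
    signal averaging into a single composite CI formula. Ships the 27-animal
    study table as a plain-text fixture, a synthetic-data generator with known
    ground truth, and a parameter-recovery harness.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
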