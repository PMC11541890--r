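Package: voltscreen
Title: Voltammetric Screening and Chemometric Classification of Synthetic
    Cathinones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rule-based screening of synthetic cathinones from
    differential pulse voltammetry (DPV) traces recorded on a boron-doped
    diamond electrode. Ships a curated library of per-analyte peak
    fingerprints, a synthetic voltammogram generator with replicate noise and
    a 46-sample seized-panel fixture, preprocessing (window cropping,
    iterative polynomial baseline subtraction, normalization), peak detection
    and window matching, the R1/R2 cathodic positivity rule with assignment
    to six structural groups, unsupervised chemometrics (PCA and hierarchical
    clustering), and calibration statistics (LOD, LOQ, linear range,
    repeatability).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
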