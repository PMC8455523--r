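Package: sexcoex
Title: Sex-Biased Gene Co-Expression via Population Gradient Sweeps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genes whose co-expression connectivity depends on sex by
    sweeping a soft-threshold (WGCNA-style, exponent 5) connectivity statistic
    across equal-size populations that shift one sample at a time from
    all-female to all-male. Connectivity trajectories are quintilized, the
    log2-fold change between the extreme quintiles is thresholded, and calls
    are required to be consistent across repeated randomized sweeps. A
    random-population permutation null calibrates the count of threshold-passing
    genes, and a menopause variant sweeps females over an age-50 dichotomy.
    Includes sample/tissue/gene filtering rules for TPM expression data,
    exact hypergeometric over-representation analysis against GMT gene-set
    collections, evidence-score filtering of gene-disease association tables,
    set-overlap permutation tests, and a synthetic-data generator that plants
    sex-dependent co-expression modules for end-to-end validation.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
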