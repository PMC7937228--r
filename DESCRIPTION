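Package: roughrules
Title: Interpretable Rule-Based Classification with Rough Sets
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns transparent IF-THEN rule models from decision tables
    using rough set theory.  Computes decision-relative discernibility
    functions and reducts (exhaustive minimal hitting sets, the Johnson
    greedy heuristic, and a genetic-algorithm search), induces rules with
    full statistics (support, coverage, accuracy, hypergeometric
    significance with multiple-testing correction, risk ratios, support
    sets), trains class-balanced models by undersampling ensembles,
    predicts by normalized rule voting with cross-validation and
    permutation testing, generates synthetic decision tables with a
    controlled covariance structure, and exports rule models as
    co-prediction networks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
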