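Package: bcmicrosim
Title: Discrete-Event Microsimulation of Chemotherapy Omission in
    Node-Positive Breast Cancer
Version: 1.0.0
Authors@R:
    person("bcmicrosim", "developers", role = c("aut", "cre"),
           email = "bcmicrosim@example.org")
Description: Simulates population-level outcomes of omitting adjuvant
    chemotherapy in women with hormone-receptor-positive, HER2-negative,
    node-positive (1-3 nodes) breast cancer and a 21-gene recurrence score
    of 25 or less. Provides a virtual population generator driven by a
    conditional covariate distribution chain, a competing-risk event engine
    (distant recurrence, breast cancer death, other-cause death) with
    menopause-specific chemotherapy effects and empirical-Bayes treatment
    effect sampling, Kaplan-Meier distant recurrence-free survival,
    life-year and discounted quality-adjusted life-year accounting,
    calibration of unpublished hazard parameters to published aggregate
    tables, a virtual-trial validation harness, and a sensitivity-analysis
    suite.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table (>= 1.14.0),
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
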