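Package: rvpsim
Title: Virtual-Population Simulation of Hypertension Treatment Guidelines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates seeded, stratified virtual populations of 35-64
    year-olds with correlated cardiovascular risk factors, scores each
    individual's 10-year risk of fatal cardiovascular disease with the
    SCORE low-risk-region equations, applies historical and current
    hypertension-treatment eligibility rules (fixed blood-pressure
    thresholds and the ESC blood-pressure-grade by risk-category grid),
    and quantifies the public-health impact of each rule as expected
    events prevented and eligible subjects per event prevented.  A
    comparison layer contrasts simulated eligibility with observed
    survey treatment rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    tools,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
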