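Package: orthocea
Title: Decision-Tree Cost-Effectiveness Analysis of Interceptive Orthodontics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-analytic evaluation of early (interceptive) orthodontic
    treatment strategies against comprehensive fixed-appliance therapy from a
    public payer perspective. Implements a decision tree with initial
    (success/partial success/failure) and long-term (stable/relapse) outcomes,
    discounted expected costs and effects, incremental analysis on the
    cost-effectiveness plane, cost-neutrality (minimum required effectiveness)
    thresholds, probabilistic sensitivity analysis with calibrated
    Dirichlet-distributed outcome probabilities, deterministic one-way scenario
    analysis, and a synthetic registry-cohort generator for patient-level data
    with multinomial outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
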