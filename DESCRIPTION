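Package: switchbox
Title: Active Causal Learning Analysis for the Sparse/Dense Switch-Box Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Task model, Bayesian ideal observer and analysis pipeline for a
    six-switch causal search task in which a single hidden switch is either
    the only working one (sparse condition) or the only broken one (dense
    condition). Provides deterministic outcome simulation and candidate-set
    belief updating, expected information gain (EIG) of interventions and
    per-trial efficiency relative to the EIG-optimal choice, seeded simulated
    learners (random, test-one, split-half, greedy-EIG), session-level
    strategy classification with an information-optimality flag, token-economy
    payout accounting with exact expected-reward evaluation of policies,
    exact 2x2 contingency inference, bootstrap summaries and simulation-based
    power analysis for two-proportion Fisher tests, and a seeded synthetic
    participant-cohort generator with CSV trial-log round-tripping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
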