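Package: osteosim
Title: Individual-Level Markov Microsimulation for Osteoporosis Treatment
    Cost-Effectiveness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-level (Markov microsimulation) state-transition
    model for the cost-effectiveness of anti-osteoporotic drug therapy in
    postmenopausal women, parameterised for the Chinese healthcare-payer
    setting. Women are simulated one at a time through annual cycles from
    therapy initiation to death or age 105, tracking hip, clinical vertebral,
    wrist and other osteoporotic fractures, hip-fracture excess mortality,
    medication persistence and compliance, and the linear offset of the
    treatment effect after discontinuation. The package computes lifetime
    discounted costs and quality-adjusted life-years, incremental
    cost-effectiveness ratios, net monetary and net health benefit, one-way
    deterministic sensitivity analyses (tornado diagrams), two-level
    probabilistic sensitivity analyses with cost-effectiveness acceptability
    curves, and adherence scenario analyses, using common random numbers for
    paired strategy comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
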