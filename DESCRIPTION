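Package: fmcea
Title: Markov Cohort Cost-Effectiveness Modeling of Fibromyalgia Pharmacotherapies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-state (mild, moderate, severe, dead) annual-cycle Markov
    cohort model for comparing pharmacologic strategies in fibromyalgia, with
    age-stratified background mortality from a life table, half-cycle
    correction and discounting; an economics layer computing lifetime
    discounted costs and QALYs by perspective, ICERs, incremental net monetary
    benefit, and the efficiency frontier under strong and extended dominance;
    deterministic one-way sensitivity analysis (tornado) and probabilistic
    sensitivity analysis via second-order Monte Carlo with moment-matched
    beta, gamma and lognormal parameter distributions and
    cost-effectiveness acceptability curves; and a synthetic input generator
    producing complete, internally consistent model parameter sets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
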