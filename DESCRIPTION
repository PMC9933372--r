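Package: lumbarCUA
Title: Lifetime Cost-Utility Analysis of Lateral Versus Posterior Lumbar
    Interbody Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-analytic cost-utility model comparing lateral (LLIF)
    and open posterior (PLIF) single-level lumbar interbody fusion from a
    societal perspective over a lifetime horizon.  Implements a short-term
    decision tree feeding a five-state annual-cycle Markov cohort model
    (well, complications, index revision, adjacent revision, death) with
    background mortality, 3% discounting and QALY accumulation; incremental
    cost-effectiveness ratios and net monetary benefit against a
    willingness-to-pay threshold; one-way deterministic sensitivity analysis
    (tornado) and probabilistic sensitivity analysis with beta/gamma
    moment-matched parameter distributions, cost-effectiveness plane,
    acceptability curves and the switch-point willingness-to-pay.  A
    synthetic patient-level cohort generator reproduces the summary
    statistics of the source registry so the utility-estimation stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    lhs,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
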