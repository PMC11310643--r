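Package: dalyeval
Title: Trial-Based Economic Evaluation with DALY Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-part, config-driven economic evaluation pipeline for
    two-arm trials with binary outcomes: a cost analysis from payer and
    combined payer-patient perspectives, a probabilistic cost-effectiveness
    analysis that converts absolute risk differences into disability-adjusted
    life years (DALYs) averted via moment-matched Monte Carlo simulation, and
    a multi-year budget impact projection for programme scale-up. Includes a
    synthetic two-arm trial generator for validating the estimators the
    pipeline consumes, incremental cost-effectiveness ratios, net monetary
    benefit, cost-effectiveness acceptability frontiers, and break-even
    threshold analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
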