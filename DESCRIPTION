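Package: myopiaCEA
Title: Markov Cohort Cost-Effectiveness Analysis of School-Based Myopia
    Prevention and Control Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A four-state, age-structured Markov cohort model of myopia
    onset and progression in schoolchildren (ages 6 to 18), with a full
    economic evaluation layer: quality-adjusted and disability-adjusted
    life-years, discounted societal costs across a school screening and
    referral cascade, incremental cost-utility and cost-effectiveness
    ratios with strict and extended dominance, WHO GDP-multiple
    willingness-to-pay thresholds, one-way (tornado) and probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves,
    and perfect-compliance subgroup scenarios. Because the parameter
    appendix of the motivating national evaluation is not publicly
    available, the package ships a calibration module that fits a
    clearly labelled surrogate parameter set to the published baseline
    prevalences, age-18 prevalences per strategy, and per-person cost,
    QALY and DALY anchors, so the whole pipeline is reproducible from
    plain-text inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
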