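Package: ceamarkov
Title: Three-State Markov Cohort Cost-Effectiveness Modelling for Oncology
    Treatment Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic modelling toolkit built around a three-state
    (stable, progressive, dead) Markov cohort model for comparing the
    cost-effectiveness of two oncology treatment strategies. Converts median
    progression-free and overall survival into per-cycle transition
    probabilities under a constant-hazard assumption, accrues discounted
    life-years, quality-adjusted life-years and costs, and computes
    incremental cost-effectiveness ratios, net monetary benefit and dominance
    verdicts. Includes one-way (tornado) sensitivity analysis, probabilistic
    sensitivity analysis with method-of-moments beta/gamma distributions,
    cost-effectiveness acceptability curves, a synthetic two-arm trial
    generator with exponential event times, and a bundled reference parameter
    set for first-line anlotinib versus sunitinib in metastatic renal cell
    carcinoma.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
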