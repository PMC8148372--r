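Package: bpscreen
Title: Cost-Effectiveness of Two-Step Blood Pressure Screening in Dental Care
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Health-economic evaluation of an opportunistic two-step
    hypertension screening programme delivered during routine dental
    check-ups, compared with usual care. Provides a short-term costing
    model (cost per identified case of hypertension, payer and societal
    perspectives), a 20-year six-state Markov cohort model with
    Framingham-based annual risks of acute myocardial infarction and
    stroke, life-table background mortality, and discounted costs and
    quality-adjusted life years (QALYs), together with deterministic
    (tornado) and probabilistic sensitivity analyses, cost-effectiveness
    plane and acceptability-curve summaries, and a synthetic cohort and
    screening-cascade generator so every stage can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
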