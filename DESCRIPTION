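Package: contcea
Title: Decision-Analytic Cost-Effectiveness Model of Nurse-Led Continence Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision tree feeding a three-state Markov cohort model for
    urinary incontinence care in multimorbid community-dwelling elderly,
    comparing usual primary care with a care pathway led by a continence
    nurse specialist. Computes per-patient costs by payer and societal
    perspective, quality-adjusted life years, national budget impact with
    mortality and nursing-home attrition, one-way and probabilistic
    sensitivity analyses, scenario analyses and incremental
    cost-effectiveness ratios. Includes a synthetic life-table generator and
    an independent individual-level microsimulation used to cross-validate
    the cohort engine.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
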