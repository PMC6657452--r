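Package: catqol
Title: Adaptive Quality-of-Life Assessment, Tailored Feedback, and
    Acceptability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing computerized adaptive
    quality-of-life (QoL) assessment experiments. Implements Rasch
    partial credit model (PCM) primitives with maximum-likelihood trait
    estimation, an adaptive test engine with maximum-information item
    selection and a standard-error stopping rule, fixed-length
    questionnaire scoring on the 0-100 scale, deterministic graphical and
    tailored text feedback generation, and the ordinal psychometrics used
    to evaluate assessment acceptability: Cliff's delta with confidence
    intervals, tie-corrected Wilcoxon rank-sum tests, Mokken scalability
    (Loevinger's H) with automated item selection, and Cronbach's alpha.
    A seeded synthetic-data module generates item banks, latent traits,
    item responses and six-condition acceptability surveys with
    calibrated population effect sizes, and a pipeline orchestrates the
    full experiment analogue from attention filtering to effect-size
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
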