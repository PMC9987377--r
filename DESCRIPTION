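Package: alswear
Title: Longitudinal Modelling of Wearable Activity and Self-Entry Surveys in ALS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying disease progression in amyotrophic lateral
    sclerosis (ALS) from continuously worn activity monitors and smartphone
    self-entry surveys. Simulates a longitudinal digital-phenotyping cohort
    (minute-level activity counts or step counts with circadian structure,
    non-wear and charging gaps, and survey trajectories coupled to a latent
    severity process), classifies valid wear hours and days per device,
    imputes missing minute-level activity counts, derives daily physical
    activity measures (total activity counts, fragmentation transition
    probabilities, cadence and step-band summaries), and fits linear mixed
    models with participant-specific random intercepts and slopes, including
    marginal and conditional R-squared, conditional-mean relative-change
    summaries, survey-comparison models, windowed-covariate association
    models, and a monitoring-frequency sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    lme4,
    lmerTest,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
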