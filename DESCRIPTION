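Package: respectr
Title: Respective Patient-Selected Primary Outcomes for Wait-List Controlled Trials
Version: 0.1.0
Authors@R: person("respectr", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for clinical trials whose primary endpoint is a
    participant-selected ("respective") symptom standardized to a common
    scale: scoring of the patient-reported instrument battery (Chalder
    fatigue, MRC dyspnea, P4 pain, HADS, symptom visual analog scales),
    within-subgroup baseline standardization of the chosen-symptom score,
    covariate-adaptive allocation by Pocock-Simon minimization with a
    random element, baseline-adjusted (ANCOVA) treatment-effect
    estimation with subgroup interactions and noncentral-t power
    calculations, missing-data sensitivity analyses (multiple imputation
    by chained equations with Rubin pooling, inverse-probability-of-
    follow-up weighting), and a synthetic trial generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
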