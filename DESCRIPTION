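Package: rcstrial
Title: Simulation and Analysis of Randomized Ambulance-Dispatch
    Prioritization Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to simulate and analyse randomized trials of
    decision-support interventions for ambulance dispatch in resource
    constrained situations (RCS), where several patients await a single
    available ambulance. Provides a synthetic cohort generator with a
    latent-acuity model driving vital signs, proxy outcomes and risk
    predictions; NEWS 2 (National Early Warning Score) computation from
    vital-sign components; a weighted composite risk score with a
    median-gap confidence classifier; trial protocol machinery including
    repeat-randomization resolution and participant-flow accounting;
    multiple imputation of NEWS components by chained equations (random
    forest or predictive mean matching); Rubin's-rules pooling for
    logistic regression and rank-sum tests; and pre-specified and
    counterfactual analyses (compliance, confidence subgroups, time
    trends, drift monitoring, calibration, random baselines, and
    full-compliance and confidence-blended prioritization strategies).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    arrow
Config/testthat/edition: 3
RoxygenNote: 7.3.3
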