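Package: crscore
Title: Continuous Cognitive Resilience Scoring from Neuropathology-Informed
    Counterfactual Damage Estimates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cognitive resilience (CR) as a continuous,
    per-assessment score in autopsy cohorts. Brain damage is estimated in
    cognitive-test units by an out-of-fold machine-learning prediction of
    cognitive performance from ordinal neuropathologic lesion rankings, age
    and sex, followed by a lesion-free counterfactual substitution; CR is
    then solved from the linear identity cognitive measure = CR - damage.
    Includes a latent-variable synthetic cohort generator with known
    ground-truth reserve, compensation and damage for validating every
    pipeline stage, a CR predictor from intra-vitam demographic and medical
    features with signed feature-importance ranking (including
    sex-stratified models), and the stratified group comparisons,
    correlation matrices and covariate-adjusted linear models used to
    characterize the resulting scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
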