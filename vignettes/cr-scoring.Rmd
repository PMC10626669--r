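---
title: "Continuous cognitive resilience scoring: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous cognitive resilience scoring: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cognitive resilience (CR) is the capacity that lets some older individuals
remain cognitively normal despite carrying a neurodegenerative lesion burden
that would ordinarily cause dementia. Treated as a binary label — "high
neuropathologic burden, normal cognition" — CR captures only extreme cases
and cannot vary across cognitive domains. `crscore` instead treats CR as a
continuous, per-assessment quantity defined by a linear identity in the units
of each cognitive assessment:

$$\text{measure}_{i,a} \;=\; \text{CR}_{i,a} \;-\; \text{damage}_{i,a}$$

for individual $i$ and assessment $a$. Cognition is the balance of two
opposing terms: the damage inflicted by Alzheimer's disease and related
dementias (ADRDs), and the resilience counteracting it. CR itself decomposes
conceptually into reserve (premorbid capacity, built early in life) plus
compensation (adaptive processes engaged after damage begins); only the
boundary case is observable — when damage is zero, compensation never
engages and CR equals reserve equals the measured cognition. The package
represents that decomposition in its synthetic generator but never claims to
estimate reserve or compensation separately from real data, because no
current measurement separates them.

## Damage in cognitive-test units

The measure is observed; damage must be estimated, and it must be expressed
in the same units as the assessment for the identity to be solvable. The
estimator is a counterfactual contrast:

1. A random forest learns to predict the oriented cognitive measure from 17
   ordinal neuropathologic lesion rankings plus age at death and sex, with
   5-fold cross-validation; every individual's *actual estimate* comes from
   the model whose training split excluded them (out-of-fold purity), and
   the held-out predictions are aggregated across folds.
2. The same per-fold model — no retraining — re-scores each individual with
   their lesion block replaced by the average lesion profile of the
   lesion-free subgroup (composite neuropathology index 0), keeping their
   own age and sex. This is the *counterfactual estimate*: expected
   cognition for a person of that age and sex with essentially no lesions.
3. `damage = counterfactual − actual`.

Two conventions deserve comment because the design was genuinely open:

* **Orientation.** All assessments are converted to "larger = better
  cognition" before modelling: semantic fluency (ANIMALS), story recall
  (LOGIMEM) and digit-symbol (WAIS) pass through; trail-making B completion
  time is negated (slower = worse); the consensus diagnosis is coded
  dementia = 0, MCI = 1, NCI = 2 and treated as a fifth, ordinal regression
  target. A single orientation is what makes damage and CR sign-comparable
  across assessments — one convention, applied everywhere, so that larger
  damage always means more impairment.
* **Sign of the contrast.** Under the common orientation the lesion-free
  counterfactual predicts *higher* cognition than the actual profile, so the
  counterfactual-minus-actual difference is nonnegative in expectation and
  CR = measure + damage is at least the measure, as reserve semantics
  require. The subtraction is stored with both operands so the identity can
  be re-checked exactly on any output table.

The ordinal diagnosis is modelled as regression on its 0/1/2 code rather
than classification; it enters the identity like any other assessment, and
its coarseness is simply inherited by the resulting score.

Residuals of the actual-estimate model (measure − actual estimate) are an
alternative resilience proxy used in earlier literature;
`compute_residual_scores()` returns them and their per-assessment
correlation with the CR score. Algebraically CR − residual equals the
counterfactual estimate, so the two formulations differ exactly by the
individual-specific lesion-free baseline.

## The synthetic cohort generator

Real data of this kind (autopsy cohorts with consensus lesion rankings,
e.g. the National Alzheimer's Coordinating Center) are restricted-access,
so validation rests on `generate_cohort()`, a latent-variable generator
whose hidden truth is returned alongside the observable table:

* **Demographics**: 44% female; age at death 79 ± 12; education 15.6 ± 2.9
  years; APOE e4/e2 allele frequencies 0.25/0.08; assessment-to-autopsy
  interval 9 ± 6 months. These match published descriptions of large
  autopsy cohorts.
* **Severity → lesions**: a nonnegative latent severity grows with age past
  65 and with APOE e4 dose; each of the 17 ordinal features thresholds
  (severity + noise) at fixed cutpoints, so raising any single rank never
  lowers damage. The defaults put roughly 6–7% of individuals at an all-zero
  lesion profile, matching the lesion-free fraction such cohorts report.
* **Damage**: a per-assessment gain times the normalized weighted rank sum,
  in oriented test units. Damage is therefore a deterministic, monotone
  function of the lesion panel — exactly the assumption under which the
  counterfactual substitution identifies it.
* **Reserve and compensation**: each assessment's reserve loads (0.7) on a
  shared person-level resilience factor, plus a female advantage (0.25 sd),
  a weak education slope (0.05 sd/yr) and independent noise; compensation
  is a fixed fraction (0.3) of damage, zero whenever damage is zero. The
  shared factor is what makes CR scores correlate across assessments.
* **Measurement**: measure = CR − damage + noise; raw test scores invert
  the orientation and clip to plausible ranges (ANIMALS mean ≈ 17, sd ≈ 6,
  and so on — scale conventions, not claims); the diagnosis discretizes its
  latent measure into the three status levels.
* **Medical features**: five CR-linked features named after the health
  domains that dominate intra-vitam CR prediction (depression scale, living
  with a partner, behavioral symptoms, medication count, hearing aid), five
  cardiovascular damage-linked features, and pure-noise distractors.

What the generator does **not** emulate: longitudinal visits, realistic
missingness patterns, correlated lesion subsystems (every feature loads on
one severity axis), or any real marginal distribution of the lesion ranks.
Passing recovery tests on this generator shows the pipeline is correct and
well-calibrated *under its own assumptions* — damage identifiable from the
lesion panel, additive reserve — not that those assumptions hold in any
particular real cohort.

Two canned scenarios freeze conditions used by the validation suite:
`sim_params_allele_contrast()` (e4 acts on severity only, compensation off;
the per-allele severity effect 0.4 was calibrated once against the
generative target of a standardized difference of 0.5 in *true* damage
between carriers and non-carriers, using only the generator's truth) and
`sim_params_importance()` (5 CR-linked features among 50 distractors).

## Numerical choices

* **Exactness.** CR is stored as measure + damage, so re-checking the
  identity involves floating-point rounding of order 1e-14 on typical
  scales; the baseline-zero property (an individual whose lesion vector
  equals the baseline profile has damage 0) is exact to the bit, because
  both scorings present identical model inputs.
* **Null calibration.** Under a null generator (all damage gains zero) the
  run-level mean of estimated damage is *not* well bracketed by the naive
  1.96·sd/√n band: the counterfactual prediction at the all-zero corner of
  17 mutually correlated lesion features carries between-run extrapolation
  variance several times larger. The validation therefore uses a
  Monte-Carlo band — replicate null pipeline runs at n = 400 with 150-tree
  forests, checking that 0 lies inside the replicates' 95% interval — and
  additionally checks that the null spread of damage estimates is below
  0.75× the spread under the default gains.
* **Forests.** `ranger` with 500 trees, default mtry and depth, one thread,
  explicit seeds; no hyperparameter search. The regressor is an
  interchangeable contract (`fit`/`predict`/`importance`), so tests verify
  the out-of-fold mechanics with a training-mean stub and a fixed depth-1
  stump against hand enumeration.
* **Importance.** Impurity importances averaged over fold models and
  normalized to sum to one per assessment; a permutation alternative is
  behind `metric = "permutation"`. Signs come from the Pearson correlation
  of each feature with the out-of-fold predicted CR; zero-variance features
  get a positive sign by convention and near-zero magnitude.
* **Degenerate inputs.** Constant training targets fit with a warning;
  constant vectors min–max normalize to all zeros with a warning; a
  lesion-free subgroup of size zero is an error suggesting a laxer
  composite index; rank-deficient adjusted-model designs error with the
  collinear columns named.
* **Group statistics.** Welch t-tests and Cohen's d with pooled sd;
  unadjusted p-values throughout the characterization tables.
* **Binary-CR label.** "High burden" defaults to a composite lesion index
  at or above the cohort 75th percentile, combined with NCI status; the
  cutoff is an explicit argument because no canonical threshold exists.

## Validation problem sizes

The test suite validates recovery on a default cohort of n = 1000 (five
assessments, 5-fold, 500-tree forests), the allele contrast and importance
scenarios at n = 1000, the null Monte-Carlo at n = 400 × 12 replicates,
and exact-oracle fixtures at n = 8–20. At these sizes the observed
recoveries are Pearson r ≈ 0.82–0.93 between estimated and true damage and
r ≈ 0.66–0.87 between CR score and true CR (the ordinal diagnosis is the
weakest, as its 3-level measure discards the most information), with the
damage-only allele effect appearing in estimated damage at d ≈ 0.3–0.5 and
in estimated CR at |d| < 0.1.

## Limitations

The linear identity is deliberately simple; it cannot separate reserve from
compensation, and it inherits every imperfection of the damage model —
lesion panels lack synaptic and atrophy measures, so "damage" means damage
as evidenced by consensus lesion rankings. CR scores for the ordinal
diagnosis are coarse. The generator's single-severity-axis lesion model
understates the block structure of real neuropathology; cross-assessment
correlation patterns on synthetic data should be read qualitatively only.
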