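#' Parameters for the synthetic cohort generator
#'
#' Bundles every knob of the latent-variable generative model behind
#' [generate_cohort()]. The chain is: demographics and APOE alleles are
#' sampled; a nonnegative latent neurodegenerative severity accumulates with
#' age past an onset and with APOE e4 dose; ordinal lesion ranks are sampled
#' monotonically in severity; true damage per assessment is a gain times a
#' weighted normalized rank sum; reserve is drawn from a person-level
#' resilience factor shared across assessments (plus sex and education
#' effects); compensation is a fixed fraction of damage; the oriented
#' cognitive measure is CR - damage plus measurement noise; raw test scores
#' invert the orientation map and clip to each test's raw range; and medical
#' features are linear functions of the resilience factor (CR-linked), of
#' lesion burden (damage-linked), or pure noise (distractors).
#'
#' @param n Number of individuals.
#' @param seed Integer seed; the generator is bit-reproducible given the seed.
#' @param schema A [np_schema()].
#' @param registry Assessment registry (see [default_registry()]).
#' @param severity List: `base`, `age_slope` (per year past `age_onset`),
#'   `age_onset`, `apoe_e4` and `apoe_e2` additive effects per allele, `sd`
#'   of the individual noise. Severity is truncated at 0.
#' @param np List: `loading` (per-feature weight on severity; default all 1),
#'   `threshold_base` and `threshold_step` defining the ordinal cutpoints
#'   `base + step * 0:(L-2)`, and `noise_sd` of the per-feature jitter.
#' @param assessments Data frame with one row per assessment: `assessment`,
#'   `damage_gain` (oriented test units per unit normalized lesion burden),
#'   `reserve_mean`, `reserve_sd`, `noise_sd` (all in oriented units).
#' @param reserve List: `common_loading` (correlation loading of each
#'   assessment's reserve on the shared person-level factor), `sex_effect`
#'   (additive effect for females, in units of `reserve_sd`), `educ_slope`
#'   (per year of education, in units of `reserve_sd`).
#' @param compensation_frac Fraction of damage offset by compensation, in
#'   \[0, 1\]. Compensation is identically 0 when damage is 0.
#' @param demographics List of marginal parameters: `p_female`, `age_mean`,
#'   `age_sd`, `educ_mean`, `educ_sd`, `e4_freq`, `e2_freq` (per-allele
#'   frequencies), `interval_mean`, `interval_sd` (months).
#' @param medical List: `n_cr`, `n_damage`, `n_distractor` feature counts,
#'   `n_cr_female` (CR-linked in females only, noise in males), `effect_cr`
#'   and `effect_damage` (latent signal-to-noise loadings).
#'
#' @return A list of class `cr_sim_params`.
#' @export
sim_params <- function(n = 1000L,
                       seed = 20231106L,
                       schema = np_schema(),
                       registry = default_registry(),
                       severity = list(),
                       np = list(),
                       assessments = NULL,
                       reserve = list(),
                       compensation_frac = 0.3,
                       demographics = list(),
                       medical = list()) {
  n <- as.integer(n)
  stopifnot(n >= 0L, is.numeric(seed), length(seed) == 1L)
  severity <- utils::modifyList(
    list(base = 0.4, age_slope = 0.035, age_onset = 65,
         apoe_e4 = 0.5, apoe_e2 = -0.2, sd = 0.8),
    severity)
  np <- utils::modifyList(
    list(loading = rep(1, length(schema$feature_names)),
         threshold_base = 0.5, threshold_step = 0.75, noise_sd = 0.3),
    np)
  if (length(np$loading) != length(schema$feature_names) || any(np$loading < 0)) {
    stop("np$loading must be nonnegative with one weight per feature", call. = FALSE)
  }
  if (is.null(assessments)) {
    assessments <- data.frame(
      assessment  = c("ANIMALS", "LOGIMEM", "TRAILB", "WAIS", "NACCUDSD"),
      damage_gain = c(12, 10, 120, 24, 2.0),
      reserve_mean = c(20, 12, -90, 40, 2.0),
      reserve_sd   = c(4, 3.5, 30, 8, 0.5),
      noise_sd     = c(2, 1.5, 15, 4, 0.2),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(setequal(assessments$assessment, assessment_names(registry)),
            all(assessments$damage_gain >= 0), all(assessments$reserve_sd >= 0),
            all(assessments$noise_sd >= 0))
  reserve <- utils::modifyList(
    list(common_loading = 0.7, sex_effect = 0.25, educ_slope = 0.05),
    reserve)
  stopifnot(compensation_frac >= 0, compensation_frac <= 1)
  demographics <- utils::modifyList(
    list(p_female = 0.44, age_mean = 79, age_sd = 12,
         educ_mean = 15.6, educ_sd = 2.9,
         e4_freq = 0.25, e2_freq = 0.08,
         interval_mean = 9, interval_sd = 6),
    demographics)
  medical <- utils::modifyList(
    list(n_cr = 5L, n_damage = 5L, n_distractor = 50L, n_cr_female = 0L,
         effect_cr = 1.0, effect_damage = 1.0),
    medical)
  structure(
    list(n = n, seed = as.integer(seed), schema = schema, registry = registry,
         severity = severity, np = np, assessments = assessments,
         reserve = reserve, compensation_frac = compensation_frac,
         demographics = demographics, medical = medical),
    class = "cr_sim_params"
  )
}

# Named CR-linked and damage-linked medical features, mirroring the health
# domains that dominate intra-vitam CR prediction (mood/behavioral symptoms,
# social support, medication burden, hearing, cardiovascular measures).
# sign: generative direction of association with the latent factor.
MED_CR_LIBRARY <- data.frame(
  name  = c("med_gds", "med_living_partner", "med_behav_symptoms",
            "med_n_medications", "med_hearing_aid"),
  sign  = c(-1, 1, -1, -1, -1),
  binary = c(FALSE, TRUE, TRUE, FALSE, TRUE),
  mu    = c(5, NA, NA, 6, NA),
  scale = c(3, NA, NA, 2.5, NA),
  lo    = c(0, NA, NA, 0, NA),
  hi    = c(15, NA, NA, 30, NA),
  stringsAsFactors = FALSE
)

MED_DAMAGE_LIBRARY <- data.frame(
  name  = c("med_bmi", "med_heart_rate", "med_diastolic_bp",
            "med_systolic_bp", "med_weight"),
  sign  = c(1, 1, 1, -1, 1),
  binary = FALSE,
  mu    = c(27, 72, 75, 135, 75),
  scale = c(4.5, 10, 10, 18, 14),
  lo    = c(12, 40, 40, 80, 35),
  hi    = c(55, 130, 120, 220, 160),
  stringsAsFactors = FALSE
)

med_feature_values <- function(latent, row) {
  if (isTRUE(row$binary)) {
    as.integer(latent > 0)
  } else if (!is.na(row$mu)) {
    pmin(pmax(round(row$mu + row$scale * latent, 1), row$lo), row$hi)
  } else {
    latent
  }
}

#' Generate a synthetic autopsy cohort with known latent truth
#'
#' Simulates a NACC-like cohort table together with the hidden reserve,
#' compensation, damage and CR values that produced it, so that damage
#' estimation, CR scoring, CR prediction and the characterization analyses
#' can all be validated against ground truth without any restricted data.
#'
#' @param params A [sim_params()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{cohort}{validated cohort data frame (see [read_cohort()]).}
#'     \item{truth}{long data frame, one row per individual and assessment:
#'       `id`, `assessment`, `true_reserve`, `true_compensation`,
#'       `true_damage`, `true_cr`, `noiseless_measure`. The identity
#'       `true_cr - true_damage = noiseless_measure` holds exactly, and
#'       compensation is 0 wherever damage is 0.}
#'     \item{individuals}{per-individual latent variables: `id`, `severity`,
#'       `np_burden` (normalized weighted rank sum in \[0, 1\]),
#'       `cr_factor` (the shared resilience factor).}
#'   }
#' @export
generate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "cr_sim_params"))
  n <- params$n
  schema <- params$schema
  registry <- params$registry
  empty <- function() {
    cohort <- as_cohort(empty_cohort_frame(schema, registry), schema, registry)
    list(cohort = cohort,
         truth = data.frame(id = character(), assessment = character(),
                            true_reserve = numeric(), true_compensation = numeric(),
                            true_damage = numeric(), true_cr = numeric(),
                            noiseless_measure = numeric(), stringsAsFactors = FALSE),
         individuals = data.frame(id = character(), severity = numeric(),
                                  np_burden = numeric(), cr_factor = numeric(),
                                  stringsAsFactors = FALSE))
  }
  if (n == 0L) return(empty())

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(params$seed)

  dem <- params$demographics
  id <- sprintf("S%05d", seq_len(n))
  sex <- ifelse(stats::runif(n) < dem$p_female, "female", "male")
  female <- as.integer(sex == "female")
  age <- pmin(pmax(stats::rnorm(n, dem$age_mean, dem$age_sd), 50), 110)
  educ <- pmin(pmax(round(stats::rnorm(n, dem$educ_mean, dem$educ_sd)), 6), 25)
  # two independent alleles per person; e4 and e2 compete for each slot
  draw_alleles <- function() {
    u <- stats::runif(n)
    ifelse(u < dem$e4_freq, "e4", ifelse(u < dem$e4_freq + dem$e2_freq, "e2", "e3"))
  }
  a1 <- draw_alleles(); a2 <- draw_alleles()
  apoe_e4 <- (a1 == "e4") + (a2 == "e4")
  apoe_e2 <- (a1 == "e2") + (a2 == "e2")
  interval <- round(pmax(stats::rnorm(n, dem$interval_mean, dem$interval_sd), 0), 1)

  sv <- params$severity
  severity <- pmax(0, sv$base +
                     sv$age_slope * pmax(age - sv$age_onset, 0) +
                     sv$apoe_e4 * apoe_e4 + sv$apoe_e2 * apoe_e2 +
                     stats::rnorm(n, 0, sv$sd))

  # ordinal lesion ranks: shared severity pushed through per-feature
  # thresholds with independent jitter; monotone nondecreasing in severity
  npp <- params$np
  n_feat <- length(schema$feature_names)
  ranks <- matrix(0L, n, n_feat, dimnames = list(NULL, np_cols(schema)))
  for (j in seq_len(n_feat)) {
    latent <- npp$loading[j] * severity + stats::rnorm(n, 0, npp$noise_sd)
    taus <- npp$threshold_base +
      npp$threshold_step * (0:(schema$levels_per_feature[j] - 2L))
    ranks[, j] <- rowSums(outer(latent, taus, `>`))
  }
  w <- npp$loading
  denom <- sum(w * (schema$levels_per_feature - 1L))
  np_burden <- if (denom > 0) as.numeric(ranks %*% w) / denom else rep(0, n)

  rs <- params$reserve
  cr_factor <- stats::rnorm(n)
  lam <- rs$common_loading
  a_tab <- params$assessments
  a_tab <- a_tab[match(assessment_names(registry), a_tab$assessment), ]

  truth_list <- vector("list", nrow(a_tab))
  cohort <- data.frame(id = id, sex = sex, age_death = round(age, 1),
                       educ = educ, apoe_e4 = apoe_e4, apoe_e2 = apoe_e2,
                       status = NA_character_, interval_months = interval,
                       stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(ranks))

  for (k in seq_len(nrow(a_tab))) {
    a <- a_tab[k, ]
    spec <- registry[[a$assessment]]
    res <- a$reserve_mean + a$reserve_sd *
      (lam * cr_factor + sqrt(max(0, 1 - lam^2)) * stats::rnorm(n) +
         rs$sex_effect * female + rs$educ_slope * (educ - dem$educ_mean))
    dmg <- a$damage_gain * np_burden
    comp <- params$compensation_frac * dmg
    cr <- res + comp
    noiseless <- cr - dmg
    measured <- noiseless + stats::rnorm(n, 0, a$noise_sd)
    if (spec$kind == "ordinal_diagnosis") {
      code <- pmin(pmax(round(measured), spec$raw_range[1]), spec$raw_range[2])
      cohort$status <- code_to_status(code)
    } else {
      raw <- if (spec$higher_is_better) measured else -measured
      raw <- pmin(pmax(round(raw, 1), spec$raw_range[1]), spec$raw_range[2])
      cohort[[paste0("test_", spec$name)]] <- raw
    }
    truth_list[[k]] <- data.frame(
      id = id, assessment = a$assessment,
      true_reserve = res, true_compensation = comp,
      true_damage = dmg, true_cr = cr, noiseless_measure = noiseless,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_list)
  rownames(truth) <- NULL

  med <- params$medical
  dmg_factor <- as.numeric(scale(np_burden))
  if (stats::sd(np_burden) == 0) dmg_factor <- rep(0, n)
  add_block <- function(cohort, k_want, library, factor_vec, effect, prefix) {
    if (k_want <= 0L) return(cohort)
    for (j in seq_len(k_want)) {
      if (j <= nrow(library)) {
        row <- library[j, ]
      } else {
        row <- data.frame(name = sprintf("%s%02d", prefix, j), sign = 1,
                          binary = FALSE, mu = NA, scale = NA, lo = NA, hi = NA)
      }
      latent <- row$sign * effect * factor_vec + stats::rnorm(n)
      cohort[[row$name]] <- med_feature_values(latent, row)
    }
    cohort
  }
  cohort <- add_block(cohort, med$n_cr, MED_CR_LIBRARY, cr_factor,
                      med$effect_cr, "med_cr")
  cohort <- add_block(cohort, med$n_damage, MED_DAMAGE_LIBRARY, dmg_factor,
                      med$effect_damage, "med_dam")
  if (med$n_cr_female > 0L) {
    for (j in seq_len(med$n_cr_female)) {
      latent <- ifelse(female == 1L, med$effect_cr * cr_factor, 0) + stats::rnorm(n)
      cohort[[sprintf("med_fcr%02d", j)]] <- latent
    }
  }
  if (med$n_distractor > 0L) {
    for (j in seq_len(med$n_distractor)) {
      cohort[[sprintf("med_x%02d", j)]] <- stats::rnorm(n)
    }
  }

  list(cohort = as_cohort(cohort, schema, registry),
       truth = truth,
       individuals = data.frame(id = id, severity = severity,
                                np_burden = np_burden, cr_factor = cr_factor,
                                stringsAsFactors = FALSE))
}

#' Canned generator scenarios
#'
#' Named parameterizations used by the validation experiments:
#' \describe{
#'   \item{`sim_params_allele_contrast()`}{a risk-allele contrast in which
#'     APOE e4 acts on latent severity only (no compensation, no allele
#'     effect on reserve), calibrated so the standardized difference
#'     (Cohen's d) in true damage between carriers and non-carriers is about
#'     0.5 while the difference in true CR is 0 by construction. Used to
#'     check that the pipeline separates damage effects from CR effects.}
#'   \item{`sim_params_importance()`}{five CR-linked medical features among
#'     fifty pure-noise distractors (no damage-linked features), for testing
#'     that signed feature-importance ranking recovers the real predictors
#'     and their generative directions.}
#' }
#'
#' @param n,seed Passed to [sim_params()].
#' @return A `cr_sim_params` object.
#' @export
sim_params_allele_contrast <- function(n = 1000L, seed = 20231106L) {
  sim_params(n = n, seed = seed, compensation_frac = 0,
             severity = list(apoe_e4 = 0.4, apoe_e2 = 0))
}

#' @rdname sim_params_allele_contrast
#' @export
sim_params_importance <- function(n = 1000L, seed = 20231106L) {
  sim_params(n = n, seed = seed,
             medical = list(n_cr = 5L, n_damage = 0L, n_distractor = 50L))
}

empty_cohort_frame <- function(schema, registry) {
  base <- data.frame(id = character(), sex = character(), age_death = numeric(),
                     educ = numeric(), apoe_e4 = integer(), apoe_e2 = integer(),
                     status = character(), interval_months = numeric(),
                     stringsAsFactors = FALSE)
  for (col in np_cols(schema)) base[[col]] <- integer()
  for (col in test_cols(registry)) base[[col]] <- numeric()
  base
}

#' Identify resistant individuals
#'
#' Resistant individuals carry no neuropathologic lesions into late life:
#' every ordinal rank is 0 and true damage is 0 for every assessment. For
#' these individuals CR equals reserve exactly (compensation never engages).
#'
#' @param truth Latent-truth table from [generate_cohort()].
#' @param cohort Matching cohort (supplies the lesion rankings).
#' @return Character vector of resistant ids (possibly empty).
#' @export
resistant_subset <- function(truth, cohort) {
  npc <- np_cols(cohort_schema(cohort))
  np_zero <- rowSums(as.matrix(cohort[, npc, drop = FALSE]) != 0) == 0
  dmg_zero <- tapply(truth$true_damage, truth$id, function(d) all(d == 0))
  ids <- cohort$id[np_zero & unname(dmg_zero[cohort$id])]
  ids[!is.na(ids)]
}
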