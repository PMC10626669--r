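test_that("predictor matrix keeps intra-vitam columns only", {
  gen <- generate_cohort(sim_params(n = 50, seed = 41))
  cohort <- apply_eligibility(gen$cohort)
  x <- build_predictor_matrix(cohort)
  # default medical block: 5 CR-linked + 5 damage-linked + 50 distractors,
  # plus sex and education
  expect_equal(ncol(x), 62)
  expect_false(any(grepl("^np_|^test_", colnames(x))))
  expect_false(any(c("age_death", "status", "interval_months",
                     "apoe_e4", "apoe_e2") %in% colnames(x)))
  expect_identical(rownames(x), cohort$id)
  expect_false(anyNA(as.matrix(x)))

  bare <- tiny_cohort(5)
  expect_error(build_predictor_matrix(bare), "no predictors")
})

test_that("missing predictors are mean- or mode-imputed", {
  gen <- generate_cohort(sim_params(n = 30, seed = 43))
  cohort <- as.data.frame(apply_eligibility(gen$cohort))
  cohort$med_gds[2:4] <- NA
  cohort$med_living_partner[1] <- NA
  cohort <- as_cohort(cohort)
  x <- build_predictor_matrix(cohort)
  expect_equal(x$med_gds[2], mean(as.data.frame(cohort)$med_gds, na.rm = TRUE))
  obs <- as.data.frame(cohort)$med_living_partner
  mode_val <- as.numeric(names(sort(table(obs[-1]), decreasing = TRUE))[1])
  expect_equal(x$med_living_partner[1], mode_val)
})

test_that("CR predictor honours the out-of-fold contract with a mean stub", {
  set.seed(14)
  ids <- sprintf("i%02d", 1:10)
  x <- data.frame(f1 = rnorm(10), f2 = rnorm(10), row.names = ids)
  cr <- data.frame(id = ids, assessment = "WAIS",
                   cr_score = round(rnorm(10, 40, 5), 1))
  fit <- fit_cr_predictor(x, cr, "WAIS", k = 5, seed = 3,
                          regressor = regressor_mean())
  fold_of <- fit$plan$fold[match(ids, fit$plan$id)]
  y <- cr$cr_score[match(ids, cr$id)]
  oracle <- vapply(seq_along(ids), function(i) mean(y[fold_of != fold_of[i]]),
                   numeric(1))
  expect_equal(fit$predictions$predicted_cr, oracle)
})

test_that("a leaked copy of the outcome predicts it almost perfectly, and label shuffling destroys prediction", {
  gen <- generate_cohort(sim_params(n = 250, seed = 45,
                                    medical = list(n_distractor = 10L)))
  cohort <- apply_eligibility(gen$cohort)
  m <- orient_assessments(cohort)
  # deterministic small damage table so the test isolates the predictor stage
  dmg <- data.frame(id = cohort$id, assessment = "ANIMALS",
                    actual_estimate = 0, counterfactual_estimate = 0, damage = 0)
  cr <- compute_cr(m, dmg)
  x <- build_predictor_matrix(cohort)
  reg <- regressor_rf(num_trees = 100)

  x_leak <- x
  x_leak$leak <- cr$cr_score[match(rownames(x), cr$id)]
  fit_leak <- fit_cr_predictor(x_leak, cr, "ANIMALS", seed = 5, regressor = reg)
  expect_gt(fit_leak$r, 0.9)

  cr_shuf <- cr
  set.seed(6)
  cr_shuf$cr_score <- sample(cr_shuf$cr_score)
  fit_shuf <- fit_cr_predictor(x, cr_shuf, "ANIMALS", seed = 5, regressor = reg)
  expect_lt(abs(fit_shuf$r), 0.2)
  expect_gt(fit_leak$r, abs(fit_shuf$r) + 0.5)
})

test_that("importance magnitudes normalize to one and signs follow construction", {
  gen <- generate_cohort(sim_params(n = 300, seed = 47))
  cohort <- apply_eligibility(gen$cohort)
  m <- orient_assessments(cohort)
  dmg <- data.frame(id = cohort$id, assessment = "WAIS",
                    actual_estimate = 0, counterfactual_estimate = 0, damage = 0)
  cr <- compute_cr(m, dmg)
  x <- build_predictor_matrix(cohort)
  set.seed(7)
  x$anti_cr <- -cr$cr_score[match(rownames(x), cr$id)] + rnorm(nrow(x), 0, 1)
  x$flatline <- 5  # zero variance
  fit <- fit_cr_predictor(x, cr, "WAIS", seed = 9,
                          regressor = regressor_rf(num_trees = 150))
  rk <- rank_features(fit, x)
  imp <- rk$importance
  expect_true(all(imp$importance >= 0))
  expect_equal(sum(imp$importance), 1)
  expect_equal(imp$sign[imp$feature == "anti_cr"], -1)
  expect_equal(imp$sign[imp$feature == "flatline"], 1)  # convention
  expect_lt(imp$importance[imp$feature == "flatline"], 0.01)
  expect_equal(imp$rank, seq_len(nrow(imp)))
})

test_that("sex-stratified models require both strata and find sex-specific signal", {
  gen <- generate_cohort(sim_params(n = 500, seed = 49,
                                    medical = list(n_cr_female = 1L,
                                                   n_distractor = 20L)))
  cohort <- apply_eligibility(gen$cohort)
  m <- orient_assessments(cohort)
  dmg <- estimate_damage(cohort, m, assessments = "ANIMALS", seed = 3,
                         regressor = regressor_rf(num_trees = 100))
  cr <- compute_cr(m, dmg)
  x <- build_predictor_matrix(cohort)
  strat <- sex_stratified_importance(cohort, x, cr, "ANIMALS", seed = 5,
                                     regressor = regressor_rf(num_trees = 150))
  expect_true("med_fcr01" %in% strat$female$importance$top$feature)
  expect_false("med_fcr01" %in% strat$male$importance$top$feature)
  # shared generative process otherwise: overlap is substantial
  expect_gte(length(strat$overlap), 3)

  females <- as_cohort(as.data.frame(cohort)[cohort$sex == "female", ])
  expect_error(
    sex_stratified_importance(females, x[females$id, ], cr, "ANIMALS"),
    "stratum 'male'"
  )
})
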