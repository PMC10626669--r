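test_that("fold plans partition ids with sizes differing by at most one", {
  ids10 <- sprintf("i%02d", 1:10)
  plan <- make_fold_plan(ids10, k = 5, seed = 1)
  expect_identical(sort(plan$id), sort(ids10))
  expect_equal(unname(as.vector(table(plan$fold))), rep(2L, 5))

  plan11 <- make_fold_plan(c(ids10, "i11"), k = 5, seed = 1)
  expect_equal(sort(as.vector(table(plan11$fold)), decreasing = TRUE),
               c(3L, 2L, 2L, 2L, 2L))

  expect_identical(make_fold_plan(ids10, k = 5, seed = 3),
                   make_fold_plan(ids10, k = 5, seed = 3))
  expect_false(identical(make_fold_plan(ids10, k = 5, seed = 3)$fold,
                         make_fold_plan(ids10, k = 5, seed = 4)$fold))

  expect_error(make_fold_plan(ids10[1:3], k = 5), "exceeds")
  expect_error(make_fold_plan(ids10, k = 1), "at least 2")
})

test_that("baseline profile averages the lesion-free subgroup", {
  # default composite: all ranks 0, so the profile is a zero vector
  cohort <- tiny_cohort(6, schema = np_schema(3, 4))
  cohort$np_npf01 <- c(0L, 0L, 1L, 2L, 0L, 3L)
  bl <- baseline_profile(cohort)
  expect_equal(unname(bl$profile), c(0, 0, 0))
  expect_equal(bl$n_baseline, 3)

  # composite counting only feature 1: features 2-3 averaged freely
  cohort$np_npf02 <- c(0L, 2L, 0L, 0L, 1L, 0L)
  bl2 <- baseline_profile(cohort, np_index = function(np) np[, 1])
  expect_equal(bl2$n_baseline, 3)
  expect_equal(unname(bl2$profile["np_npf02"]), 1.0)

  # nobody at index 0
  cohort$np_npf01 <- 1L
  expect_error(baseline_profile(cohort), "laxer")
})

test_that("out-of-fold estimates with a mean stub equal fold-complement means", {
  set.seed(5)
  cohort <- tiny_cohort(10)
  y <- round(rnorm(10, 20, 5), 1)
  cohort$test_ANIMALS <- y
  m <- orient_assessments(cohort)
  plan <- make_fold_plan(cohort$id, k = 5, seed = 2)
  mset <- fit_oof_models(cohort, m, "ANIMALS", plan, regressor = regressor_mean())
  est <- estimate_actual(mset, cohort)
  # oracle: for each individual, the mean of the 8 targets outside their fold
  fold_of <- plan$fold[match(cohort$id, plan$id)]
  oracle <- vapply(seq_len(10), function(i) mean(y[fold_of != fold_of[i]]),
                   numeric(1))
  expect_equal(est$estimate, oracle)

  # mean stub ignores lesion features entirely: counterfactual == actual
  bl <- baseline_profile(cohort)
  cf <- estimate_counterfactual(mset, cohort, bl)
  expect_equal(cf$estimate, est$estimate)
  dmg <- compute_damage(est, cf, "ANIMALS")
  expect_true(all(dmg$damage == 0))
})

test_that("overlapping fold plans and misaligned ids are rejected", {
  cohort <- tiny_cohort(6)
  m <- orient_assessments(cohort)
  plan <- make_fold_plan(cohort$id, k = 3, seed = 1)
  bad <- rbind(plan, data.frame(id = plan$id[1], fold = 2L))
  attr(bad, "k") <- 3L
  expect_error(fit_oof_models(cohort, m, "ANIMALS", bad), "more than one fold")

  other <- tiny_cohort(6)
  other$id <- paste0("Q", seq_len(6))
  expect_error(
    fit_oof_models(as_cohort(as.data.frame(other), np_schema(2, 3)), m,
                   "ANIMALS", plan),
    "ids"
  )

  a <- data.frame(id = c("x", "y"), estimate = c(1, 2))
  b <- data.frame(id = c("x", "z"), estimate = c(1, 2))
  expect_error(compute_damage(a, b, "ANIMALS"), "different ids")
})

test_that("damage is the counterfactual-minus-actual contrast", {
  a <- data.frame(id = c("x", "y"), estimate = c(7, 4))
  b <- data.frame(id = c("y", "x"), estimate = c(4, 10))
  dmg <- compute_damage(a, b, "WAIS")
  expect_equal(dmg$damage[dmg$id == "x"], 3)
  expect_equal(dmg$damage[dmg$id == "y"], 0)
  expect_equal(dmg$counterfactual_estimate - dmg$actual_estimate, dmg$damage)
})

test_that("forest estimates are invariant to cohort row order", {
  gen <- generate_cohort(sim_params(n = 80, seed = 31))
  cohort <- apply_eligibility(gen$cohort)
  m <- orient_assessments(cohort)
  plan <- make_fold_plan(cohort$id, k = 4, seed = 2)
  bl <- baseline_profile(cohort)
  reg <- regressor_rf(num_trees = 50)
  mset <- fit_oof_models(cohort, m, "WAIS", plan, regressor = reg, seed = 4)
  est1 <- estimate_actual(mset, cohort)

  perm <- sample(nrow(cohort))
  shuffled <- as_cohort(as.data.frame(cohort)[perm, ], cohort_schema(cohort))
  est2 <- estimate_actual(mset, shuffled)
  expect_equal(est2$estimate[match(est1$id, est2$id)], est1$estimate)

  # an individual whose lesion vector equals the baseline profile has
  # identical model inputs under both scorings, hence damage exactly 0
  cf <- estimate_counterfactual(mset, cohort, bl)
  npm <- as.matrix(as.data.frame(cohort)[, paste0("np_", cohort_schema(cohort)$feature_names)])
  at_baseline <- apply(npm, 1, function(r) all(r == bl$profile))
  expect_gt(sum(at_baseline), 0)
  dmg <- compute_damage(est1, cf, "WAIS")
  expect_equal(dmg$damage[at_baseline], rep(0, sum(at_baseline)))
})

test_that("refitting with the same seed reproduces out-of-fold predictions", {
  gen <- generate_cohort(sim_params(n = 60, seed = 17))
  cohort <- apply_eligibility(gen$cohort)
  m <- orient_assessments(cohort)
  plan <- make_fold_plan(cohort$id, k = 3, seed = 9)
  reg <- regressor_rf(num_trees = 50)
  e1 <- estimate_actual(fit_oof_models(cohort, m, "LOGIMEM", plan, reg, seed = 2), cohort)
  e2 <- estimate_actual(fit_oof_models(cohort, m, "LOGIMEM", plan, reg, seed = 2), cohort)
  expect_identical(e1, e2)
})
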