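test_that("cross-assessment matrix matches the closed-form Pearson formula", {
  set.seed(3)
  ids <- sprintf("i%d", 1:6)
  scores <- expand.grid(id = ids, assessment = c("A1", "A2", "A3"),
                        stringsAsFactors = FALSE)
  scores$cr_score <- round(rnorm(18, 10, 3), 2)
  # make A3 the exact negation of A2
  s2 <- scores$cr_score[scores$assessment == "A2"]
  scores$cr_score[scores$assessment == "A3"] <- -s2

  res <- cross_assessment_matrix(scores)
  expect_equal(res$r, t(res$r))
  expect_equal(unname(diag(res$r)), rep(1, 3))
  expect_equal(res$r["A2", "A3"], -1)

  # hand-computed Pearson for the A1-A2 pair
  s1 <- scores$cr_score[scores$assessment == "A1"]
  hand <- sum((s1 - mean(s1)) * (s2 - mean(s2))) /
    sqrt(sum((s1 - mean(s1))^2) * sum((s2 - mean(s2))^2))
  expect_equal(res$r["A1", "A2"], hand)
  expect_true(all(res$p[upper.tri(res$p)] >= 0 & res$p[upper.tri(res$p)] <= 1))

  few <- scores[scores$id %in% ids[1:2], ]
  expect_error(cross_assessment_matrix(few), "at least 3")
})

test_that("group comparison computes Welch t and pooled-sd Cohen's d", {
  scores <- data.frame(id = sprintf("i%d", 1:6), assessment = "WAIS",
                       cr_score = c(1, 2, 3, 2, 3, 4))
  groups <- data.frame(id = scores$id, group = rep(c("g1", "g2"), each = 3))
  res <- group_compare(scores, groups)
  expect_equal(res$mean_diff, -1)
  expect_equal(res$cohens_d, -1)  # pooled sd is exactly 1
  # swapping the label order negates both
  res_sw <- group_compare(scores, groups, group_order = c("g2", "g1"))
  expect_equal(res_sw$cohens_d, 1)
  expect_equal(res_sw$mean_diff, 1)
  # identical groups: zero difference and zero d
  same <- scores
  same$cr_score <- rep(c(1, 2, 3), 2)
  expect_equal(group_compare(same, groups)$cohens_d, 0)
  # Welch statistic agrees with stats::t.test
  tt <- t.test(c(1, 2, 3), c(2, 3, 4), var.equal = FALSE)
  expect_equal(res$t, unname(tt$statistic))
  expect_equal(res$p_value, tt$p.value)
})

test_that("covariate correlations behave under identity, independence and monotone maps", {
  set.seed(19)
  ids <- sprintf("i%02d", 1:40)
  scores <- data.frame(id = ids, assessment = "ANIMALS",
                       cr_score = rnorm(40, 20, 5))
  self <- data.frame(id = ids, value = scores$cr_score)
  expect_equal(covariate_correlation(scores, self)$estimate, 1)

  indep <- data.frame(id = ids, value = rnorm(40))
  r <- covariate_correlation(scores, indep)$estimate
  expect_lt(abs(r), qnorm(0.995) / sqrt(37))

  sp1 <- covariate_correlation(scores, indep, method = "spearman")$estimate
  mono <- data.frame(id = ids, value = exp(indep$value))
  sp2 <- covariate_correlation(scores, mono, method = "spearman")$estimate
  expect_equal(sp1, sp2)

  flat <- data.frame(id = ids, value = rep(2, 40))
  expect_error(covariate_correlation(scores, flat), "constant")
})

test_that("adjusted linear model recovers exact constructions and matches normal equations", {
  set.seed(23)
  n <- 12
  df <- tiny_cohort_frame(n)
  df$age_death <- round(rnorm(n, 80, 8), 1)
  df$educ <- sample(12:20, n, replace = TRUE)
  df$apoe_e4 <- sample(0:2, n, replace = TRUE)
  df$status <- sample(c("NCI", "MCI", "dementia"), n, replace = TRUE)
  cohort <- as_cohort(df, np_schema(2, 3))
  adnc <- data.frame(id = df$id, adnc = sample(0:3, n, replace = TRUE))

  # response equal to the sex indicator: sex coefficient 1, all else 0
  cr_sex <- data.frame(id = df$id, assessment = "WAIS",
                       cr_score = as.numeric(df$sex == "female"))
  # the residual-free fit triggers lm's perfect-fit warning by design
  res <- suppressWarnings(adjusted_linear_model(cr_sex, cohort, adnc = adnc))
  expect_equal(res$estimate[res$term == "sex_female"], 1)
  others <- res$estimate[!res$term %in% c("sex_female")]
  expect_equal(others, rep(0, length(others)), tolerance = 1e-10)

  # generic response: coefficients equal the normal-equations solution
  cr_gen <- data.frame(id = df$id, assessment = "WAIS",
                       cr_score = rnorm(n, 30, 6))
  res2 <- adjusted_linear_model(cr_gen, cohort, adnc = adnc)
  x <- cbind(1, df$age_death, as.numeric(df$sex == "female"), df$educ,
             df$apoe_e4, c(dementia = 0, MCI = 1, NCI = 2)[df$status],
             adnc$adnc)
  beta <- solve(t(x) %*% x, t(x) %*% cr_gen$cr_score)
  expect_equal(res2$estimate, as.numeric(beta))

  # duplicated covariate: rank deficiency reported
  adnc_dup <- data.frame(id = df$id, adnc = df$apoe_e4)
  expect_error(adjusted_linear_model(cr_gen, cohort, adnc = adnc_dup),
               "collinear")
})

test_that("min-max normalization maps to [0,1] and is idempotent", {
  expect_equal(minmax_normalize(c(0, 5, 10)), c(0, 0.5, 1))
  expect_warning(z <- minmax_normalize(c(3, 3)), "constant")
  expect_equal(z, c(0, 0))
  expect_error(minmax_normalize(numeric(0)), "empty")
  set.seed(29)
  for (rep in 1:5) {
    v <- rnorm(20, sample(-5:5, 1), runif(1, 0.5, 4))
    once <- minmax_normalize(v)
    expect_true(all(once >= 0 & once <= 1))
    expect_equal(minmax_normalize(once), once)
  }
})

test_that("p-values lie in [0,1] and correlation matrices are PSD", {
  run <- shared_default_run()
  cm <- cross_assessment_matrix(run$cr, value = "cr_score")
  dm <- cross_assessment_matrix(run$damage, value = "damage")
  for (res in list(cm, dm)) {
    ev <- eigen(res$r, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
    p <- res$p[upper.tri(res$p)]
    expect_true(all(p >= 0 & p <= 1))
  }
})
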