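# Shared fixture builders and stub regressors for the test suite.

# A minimal valid cohort frame with full control over every cell.
tiny_cohort_frame <- function(n, schema = np_schema(2, 3),
                              registry = default_registry()) {
  df <- data.frame(
    id = sprintf("P%02d", seq_len(n)),
    sex = rep(c("female", "male"), length.out = n),
    age_death = seq(70, by = 2, length.out = n),
    educ = rep(16, n),
    apoe_e4 = rep(0L, n),
    apoe_e2 = rep(0L, n),
    status = rep("NCI", n),
    interval_months = rep(6, n),
    stringsAsFactors = FALSE
  )
  for (col in paste0("np_", schema$feature_names)) df[[col]] <- 0L
  df$test_ANIMALS <- rep(20, n)
  df$test_LOGIMEM <- rep(10, n)
  df$test_TRAILB <- rep(100, n)
  df$test_WAIS <- rep(40, n)
  df
}

tiny_cohort <- function(n, schema = np_schema(2, 3), ...) {
  df <- tiny_cohort_frame(n, schema = schema)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  as_cohort(df, schema = schema)
}

# Deterministic linear-regression regressor (no randomness at all).
regressor_lm_stub <- function() {
  list(
    label = "linear stub",
    fit = function(x, y, seed) {
      d <- as.data.frame(x)
      d$..y <- y
      stats::lm(..y ~ ., data = d)
    },
    predict = function(model, x) unname(stats::predict(model, as.data.frame(x)))
  )
}

# Depth-1 tree with a FIXED split: mean of training y below/at vs above the
# threshold on one feature. Analytically enumerable by hand.
regressor_fixed_stump <- function(feature, threshold) {
  list(
    label = sprintf("stump(%s <= %g)", feature, threshold),
    fit = function(x, y, seed) {
      left <- x[[feature]] <= threshold
      list(left_mean = mean(y[left]), right_mean = mean(y[!left]),
           feature = feature, threshold = threshold)
    },
    predict = function(model, x) {
      ifelse(x[[model$feature]] <= model$threshold,
             model$left_mean, model$right_mean)
    }
  )
}

# Memoized heavyweight runs shared across test files (computed at most once
# per test session).
.shared <- new.env(parent = emptyenv())

shared_default_run <- function() {
  if (is.null(.shared$default)) {
    gen <- generate_cohort(sim_params(n = 1000))
    cohort <- apply_eligibility(gen$cohort)
    measures <- orient_assessments(cohort)
    damage <- estimate_damage(cohort, measures, seed = 7)
    cr <- compute_cr(measures, damage)
    .shared$default <- list(gen = gen, cohort = cohort, measures = measures,
                            damage = damage, cr = cr)
  }
  .shared$default
}

shared_allele_run <- function() {
  if (is.null(.shared$allele)) {
    gen <- generate_cohort(sim_params_allele_contrast())
    cohort <- apply_eligibility(gen$cohort)
    measures <- orient_assessments(cohort)
    damage <- estimate_damage(cohort, measures, seed = 7)
    cr <- compute_cr(measures, damage)
    .shared$allele <- list(gen = gen, cohort = cohort, measures = measures,
                           damage = damage, cr = cr)
  }
  .shared$allele
}

truth_aligned <- function(run, table) {
  key <- function(d) paste(d$id, d$assessment)
  run$gen$truth[match(key(table), key(run$gen$truth)), ]
}
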