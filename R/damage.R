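#' Build a cross-validation fold plan
#'
#' Seeded shuffle followed by a round-robin split, so fold sizes differ by at
#' most one and the assignment is reproducible. Every downstream estimate is
#' out-of-fold: an individual is always scored by the model whose training
#' split excluded them.
#'
#' @param ids Character vector of unique individual ids.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the shuffle.
#' @return A data frame (`id`, `fold`) of class `cr_fold_plan` with
#'   attributes `k` and `seed`.
#' @export
make_fold_plan <- function(ids, k = 5L, seed = 1L) {
  ids <- as.character(ids)
  k <- as.integer(k)
  if (anyDuplicated(ids)) stop("ids must be unique", call. = FALSE)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > length(ids)) {
    stop("k = ", k, " exceeds the number of individuals (", length(ids), ")",
         call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  shuffled <- sample(ids)
  fold <- rep_len(seq_len(k), length(ids))
  plan <- data.frame(id = shuffled, fold = fold, stringsAsFactors = FALSE)
  plan <- plan[match(ids, plan$id), ]
  rownames(plan) <- NULL
  structure(plan, k = k, seed = as.integer(seed),
            class = c("cr_fold_plan", "data.frame"))
}

check_fold_plan <- function(plan) {
  if (anyDuplicated(plan$id)) {
    stop("fold plan assigns some id to more than one fold", call. = FALSE)
  }
  sizes <- table(plan$fold)
  if (max(sizes) - min(sizes) > 1L) {
    stop("fold sizes differ by more than 1", call. = FALSE)
  }
  invisible(plan)
}

#' Regressor specifications
#'
#' The damage and CR-prediction models accept any regressor honouring a small
#' contract: a list with `fit(x, y, seed)` returning a fitted object,
#' `predict(model, x)` returning numeric predictions, optionally
#' `importance(model)` returning nonnegative per-feature scores, and a
#' `label`. `regressor_rf()` is the default (random forest, 500 trees);
#' `regressor_mean()` is an analytically tractable stub that predicts the
#' training-set mean, useful for verifying out-of-fold mechanics by hand.
#'
#' @param num_trees Number of trees for the forest.
#' @param ... Extra arguments passed to [ranger::ranger()].
#' @return A regressor specification list.
#' @export
regressor_rf <- function(num_trees = 500L, ...) {
  dots <- list(...)
  list(
    label = sprintf("random forest (%d trees)", num_trees),
    fit = function(x, y, seed) {
      args <- c(list(x = as.data.frame(x), y = y, num.trees = num_trees,
                     seed = seed, num.threads = 1L,
                     importance = "impurity", respect.unordered.factors = TRUE),
                dots)
      do.call(ranger::ranger, args)
    },
    predict = function(model, x) {
      stats::predict(model, data = as.data.frame(x), num.threads = 1L)$predictions
    },
    importance = function(model) ranger::importance(model)
  )
}

#' @rdname regressor_rf
#' @export
regressor_mean <- function() {
  list(
    label = "training-mean stub",
    fit = function(x, y, seed) list(mean = mean(y), p = ncol(x),
                                    names = colnames(x)),
    predict = function(model, x) rep(model$mean, nrow(x)),
    importance = function(model) {
      stats::setNames(rep(0, model$p), model$names)
    }
  )
}

# Predictor frame for the damage model: lesion ranks + age at death + sex
# (binary numeric), per the counterfactual design where only the lesion block
# is swapped out.
damage_design <- function(cohort, schema = cohort_schema(cohort)) {
  x <- as.data.frame(cohort)[, np_cols(schema), drop = FALSE]
  x$age_death <- cohort$age_death
  x$sex_female <- as.numeric(cohort$sex == "female")
  x
}

#' Lesion-free baseline profile
#'
#' Computes the feature-wise mean lesion ranking over the subgroup with a
#' composite neuropathology index of 0 (by default: all ranks exactly 0, so
#' the profile is a zero vector; an injectable composite supports laxer
#' "low-to-no lesions" definitions). This profile defines the counterfactual
#' input: each individual is re-scored with their lesion block replaced by
#' the baseline while keeping their own age and sex, yielding an age- and
#' sex-specific estimate of lesion-free cognition.
#'
#' @param cohort An eligible cohort.
#' @param np_index Function mapping the numeric matrix of lesion ranks (one
#'   row per individual) to a nonnegative composite index; individuals with
#'   index 0 form the baseline subgroup. Default: maximum rank (0 iff all
#'   ranks are 0).
#' @return A list of class `cr_baseline` with `profile` (named mean ranks)
#'   and `n_baseline`.
#' @export
baseline_profile <- function(cohort, np_index = function(np) apply(np, 1, max)) {
  schema <- cohort_schema(cohort)
  np <- as.matrix(as.data.frame(cohort)[, np_cols(schema), drop = FALSE])
  if (anyNA(np)) stop("lesion rankings must be complete", call. = FALSE)
  idx <- np_index(np)
  zero <- idx == 0
  if (!any(zero)) {
    stop("no individuals with composite neuropathology index 0; ",
         "supply a laxer np_index", call. = FALSE)
  }
  structure(
    list(profile = colMeans(np[zero, , drop = FALSE]),
         n_baseline = sum(zero)),
    class = "cr_baseline"
  )
}

#' @export
print.cr_baseline <- function(x, ...) {
  cat(sprintf("<cr_baseline> %d lesion-free individuals; mean profile range [%g, %g]\n",
              x$n_baseline, min(x$profile), max(x$profile)))
  invisible(x)
}

#' Fit per-fold damage models for one assessment
#'
#' Trains one regressor per fold on the complement of that fold, mapping
#' lesion rankings, age at death and sex to the oriented cognitive measure.
#' The ordinal diagnosis is modelled identically, as regression on its
#' oriented 0/1/2 code.
#'
#' @param cohort An eligible cohort.
#' @param measures Oriented measures from [orient_assessments()].
#' @param assessment Assessment name.
#' @param plan Fold plan from [make_fold_plan()] covering all cohort ids.
#' @param regressor Regressor specification (default [regressor_rf()]).
#' @param seed Integer seed passed to each fold's fit.
#' @return A list of class `cr_model_set`: `models` (one per fold), `plan`,
#'   `assessment`, `features`, `regressor`.
#' @export
fit_oof_models <- function(cohort, measures, assessment,
                           plan, regressor = regressor_rf(), seed = 1L) {
  check_fold_plan(plan)
  if (!assessment %in% names(measures)) {
    stop("no oriented measures for assessment ", assessment, call. = FALSE)
  }
  if (!setequal(plan$id, cohort$id)) {
    stop("fold plan ids do not match cohort ids", call. = FALSE)
  }
  y <- measures[[assessment]][match(cohort$id, measures$id)]
  if (anyNA(y)) stop("oriented measures incomplete for ", assessment, call. = FALSE)
  x <- damage_design(cohort)
  fold_of <- plan$fold[match(cohort$id, plan$id)]
  k <- attr(plan, "k")
  models <- vector("list", k)
  for (f in seq_len(k)) {
    train <- fold_of != f
    if (stats::sd(y[train]) == 0) {
      warning("constant target in training split for fold ", f,
              " (", assessment, ")", call. = FALSE)
    }
    models[[f]] <- regressor$fit(x[train, , drop = FALSE], y[train],
                                 seed = seed + f)
  }
  structure(
    list(models = models, plan = plan, assessment = assessment,
         features = colnames(x), regressor = regressor),
    class = "cr_model_set"
  )
}

oof_predict <- function(mset, x, ids) {
  plan <- mset$plan
  fold_of <- plan$fold[match(ids, plan$id)]
  if (anyNA(fold_of)) {
    stop("id(s) absent from the fold plan: ",
         paste(ids[is.na(fold_of)], collapse = ", "), call. = FALSE)
  }
  out <- numeric(length(ids))
  for (f in unique(fold_of)) {
    sel <- fold_of == f
    out[sel] <- mset$regressor$predict(mset$models[[f]], x[sel, , drop = FALSE])
  }
  out
}

#' Out-of-fold cognitive estimates at the individual's own lesion profile
#'
#' Each individual is scored by the model of the fold that held them out;
#' predictions are aggregated across folds into one estimate per individual.
#'
#' @param mset A `cr_model_set` from [fit_oof_models()].
#' @param cohort The cohort the fold plan covers.
#' @return Data frame (`id`, `estimate`) in oriented units.
#' @export
estimate_actual <- function(mset, cohort) {
  x <- damage_design(cohort)
  data.frame(id = cohort$id,
             estimate = oof_predict(mset, x, cohort$id),
             stringsAsFactors = FALSE)
}

#' Counterfactual cognitive estimates at the lesion-free baseline
#'
#' Re-scores every individual with the same per-fold model (no retraining),
#' substituting the baseline lesion profile for their own rankings while
#' keeping their age at death and sex.
#'
#' @inheritParams estimate_actual
#' @param baseline A `cr_baseline` from [baseline_profile()].
#' @return Data frame (`id`, `estimate`) in oriented units.
#' @export
estimate_counterfactual <- function(mset, cohort, baseline) {
  stopifnot(inherits(baseline, "cr_baseline"))
  x <- damage_design(cohort)
  npc <- intersect(names(baseline$profile), colnames(x))
  if (length(npc) != length(baseline$profile)) {
    stop("baseline profile features not found in the cohort design", call. = FALSE)
  }
  for (col in npc) x[[col]] <- baseline$profile[[col]]
  data.frame(id = cohort$id,
             estimate = oof_predict(mset, x, cohort$id),
             stringsAsFactors = FALSE)
}

#' Damage as the counterfactual-minus-actual contrast
#'
#' Damage for individual i on assessment a is the drop from the lesion-free
#' counterfactual estimate to the actual estimate, in oriented test units, so
#' larger values always mean more damage. An individual whose lesion profile
#' equals the baseline has damage exactly 0.
#'
#' @param actual,counterfactual Data frames (`id`, `estimate`) from
#'   [estimate_actual()] and [estimate_counterfactual()].
#' @param assessment Assessment name recorded in the output.
#' @return Data frame (`id`, `assessment`, `actual_estimate`,
#'   `counterfactual_estimate`, `damage`).
#' @export
compute_damage <- function(actual, counterfactual, assessment) {
  if (!setequal(actual$id, counterfactual$id)) {
    stop("actual and counterfactual estimates cover different ids", call. = FALSE)
  }
  cf <- counterfactual$estimate[match(actual$id, counterfactual$id)]
  data.frame(id = as.character(actual$id), assessment = assessment,
             actual_estimate = unname(actual$estimate),
             counterfactual_estimate = unname(cf),
             damage = unname(cf - actual$estimate),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Estimate damage for one or all assessments
#'
#' Convenience pipeline: fold plan, per-fold model fits, out-of-fold actual
#' and counterfactual estimates, and the damage contrast, per assessment.
#'
#' @param cohort An eligible cohort (complete lesion block and assessments).
#' @param measures Oriented measures; computed from the cohort if `NULL`.
#' @param assessments Character vector of assessment names, or `"all"`.
#' @param k Number of folds.
#' @param seed Integer seed controlling the fold shuffle and model fits.
#' @param regressor Regressor specification.
#' @param np_index Composite index passed to [baseline_profile()].
#' @return Long data frame of damage estimates across assessments, with the
#'   `cr_baseline` attached as attribute `baseline`.
#' @export
estimate_damage <- function(cohort, measures = NULL, assessments = "all",
                            k = 5L, seed = 1L, regressor = regressor_rf(),
                            np_index = function(np) apply(np, 1, max)) {
  registry <- cohort_registry(cohort)
  if (is.null(measures)) measures <- orient_assessments(cohort)
  if (identical(assessments, "all")) assessments <- assessment_names(registry)
  plan <- make_fold_plan(cohort$id, k = k, seed = seed)
  baseline <- baseline_profile(cohort, np_index = np_index)
  out <- vector("list", length(assessments))
  for (i in seq_along(assessments)) {
    a <- assessments[i]
    mset <- fit_oof_models(cohort, measures, a, plan, regressor = regressor,
                           seed = seed + 1000L * i)
    act <- estimate_actual(mset, cohort)
    cfa <- estimate_counterfactual(mset, cohort, baseline)
    out[[i]] <- compute_damage(act, cfa, a)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "baseline") <- baseline
  attr(res, "plan") <- plan
  res
}
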