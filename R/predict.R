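#' Build the intra-vitam predictor matrix
#'
#' Assembles the feature matrix for predicting CR scores from information
#' collected during life: the medical feature block (`med_*` columns) plus
#' sex (binary numeric) and years of education. Everything knowable only at
#' or after death, or circular with the outcome, is excluded by construction:
#' lesion rankings, age/date of death, all cognitive test results, the
#' cognitive diagnosis, the autopsy interval, and APOE genotype. The
#' exclusion is asserted by name pattern before the matrix is returned.
#' Missing continuous predictors are mean-imputed, binary ones mode-imputed.
#'
#' @param cohort An eligible cohort.
#' @return Numeric data frame of predictors with rownames set to ids.
#' @export
build_predictor_matrix <- function(cohort) {
  df <- as.data.frame(cohort)
  med <- grep("^med_", names(df), value = TRUE)
  if (length(med) == 0) {
    stop("no predictors: cohort has no med_* columns", call. = FALSE)
  }
  x <- df[, med, drop = FALSE]
  x$sex_female <- as.numeric(df$sex == "female")
  x$educ <- as.numeric(df$educ)
  forbidden <- grepl("^np_|^test_", names(x)) |
    names(x) %in% c("id", "status", "age_death", "interval_months",
                    "apoe_e4", "apoe_e2")
  stopifnot(!any(forbidden))
  for (col in names(x)) {
    v <- as.numeric(x[[col]])
    if (anyNA(v)) {
      obs <- v[!is.na(v)]
      if (length(obs) == 0) stop("predictor ", col, " entirely missing", call. = FALSE)
      fill <- if (all(obs %in% c(0, 1))) {
        as.numeric(names(sort(table(obs), decreasing = TRUE))[1])
      } else {
        mean(obs)
      }
      v[is.na(v)] <- fill
    }
    x[[col]] <- v
  }
  rownames(x) <- df$id
  x
}

#' Predict CR scores from intra-vitam features
#'
#' Fits per-fold regressors (default random forest) mapping the predictor
#' matrix to the computed CR score of one assessment, aggregates out-of-fold
#' predictions, and reports the Pearson correlation between predicted and
#' computed CR -- the headline measure of how much of the autopsy-derived
#' score is recoverable during life.
#'
#' @param x Predictor matrix from [build_predictor_matrix()] (rownames = ids).
#' @param cr CR table from [compute_cr()].
#' @param assessment Assessment name.
#' @param plan Fold plan covering the ids; built internally if `NULL`.
#' @param k,seed Fold count and seed used when `plan` is `NULL`.
#' @param regressor Regressor specification (default [regressor_rf()]).
#' @return A list of class `cr_predictor_fit`: `predictions` (data frame
#'   `id`, `cr_score`, `predicted_cr`), `models`, `plan`, `assessment`,
#'   `features`, `r`, `p_value`.
#' @export
fit_cr_predictor <- function(x, cr, assessment, plan = NULL, k = 5L,
                             seed = 1L, regressor = regressor_rf()) {
  d <- cr[cr$assessment == assessment, , drop = FALSE]
  if (nrow(d) == 0) stop("no CR scores for assessment ", assessment, call. = FALSE)
  ids <- rownames(x)
  if (!setequal(ids, d$id)) {
    stop("predictor matrix and CR table cover different ids", call. = FALSE)
  }
  y <- d$cr_score[match(ids, d$id)]
  if (is.null(plan)) plan <- make_fold_plan(ids, k = k, seed = seed)
  check_fold_plan(plan)
  fold_of <- plan$fold[match(ids, plan$id)]
  if (anyNA(fold_of)) stop("fold plan does not cover all ids", call. = FALSE)
  kk <- attr(plan, "k")
  models <- vector("list", kk)
  pred <- numeric(length(ids))
  for (f in seq_len(kk)) {
    train <- fold_of != f
    models[[f]] <- regressor$fit(x[train, , drop = FALSE], y[train],
                                 seed = seed + f)
    pred[fold_of == f] <- regressor$predict(models[[f]],
                                            x[fold_of == f, , drop = FALSE])
  }
  ct <- stats::cor.test(pred, y)
  structure(
    list(predictions = data.frame(id = ids, cr_score = y, predicted_cr = pred,
                                  stringsAsFactors = FALSE),
         models = models, plan = plan, assessment = assessment,
         features = colnames(x), regressor = regressor,
         r = unname(ct$estimate), p_value = ct$p.value),
    class = "cr_predictor_fit"
  )
}

#' @export
print.cr_predictor_fit <- function(x, ...) {
  cat(sprintf("<cr_predictor_fit> %s: %d features, oof r = %.3f (p = %.3g)\n",
              x$assessment, length(x$features), x$r, x$p_value))
  invisible(x)
}

#' Signed feature-importance ranking
#'
#' Importance magnitude is the impurity-based importance averaged over the
#' fold models and normalized to sum to 1 within the assessment. Each
#' feature's sign is the sign of its Pearson correlation with the out-of-fold
#' predicted CR score (positive by convention when the correlation is
#' undefined, e.g. zero-variance features), so a negative entry reads "more
#' of this feature, lower predicted resilience". A permutation-based
#' magnitude is available via `metric = "permutation"` when the fitted
#' models support it.
#'
#' @param fit A `cr_predictor_fit`.
#' @param x The predictor matrix the fit was trained on.
#' @param metric `"impurity"` (default) or `"permutation"`; the latter
#'   requires refitting and is accepted only for forest regressors created
#'   with `ranger`.
#' @param top_k Rows to keep in the `top` view (default 10).
#' @return A list: `importance` (data frame `feature`, `importance`, `sign`,
#'   `signed_importance`, `rank`, sorted by descending magnitude) and `top`
#'   (the first `top_k` rows).
#' @export
rank_features <- function(fit, x, metric = c("impurity", "permutation"),
                          top_k = 10L) {
  metric <- match.arg(metric)
  stopifnot(inherits(fit, "cr_predictor_fit"))
  if (metric == "impurity") {
    if (is.null(fit$regressor$importance)) {
      stop("the fitted regressor does not expose importances", call. = FALSE)
    }
    imp_mat <- vapply(fit$models, fit$regressor$importance,
                      numeric(length(fit$features)))
  } else {
    ids <- rownames(x)
    fold_of <- fit$plan$fold[match(ids, fit$plan$id)]
    y <- fit$predictions$cr_score[match(ids, fit$predictions$id)]
    imp_mat <- vapply(seq_along(fit$models), function(f) {
      train <- fold_of != f
      m <- ranger::ranger(x = x[train, , drop = FALSE], y = y[train],
                          num.trees = 500L, seed = attr(fit$plan, "seed") + f,
                          num.threads = 1L, importance = "permutation")
      ranger::importance(m)
    }, numeric(length(fit$features)))
  }
  mag <- rowMeans(pmax(imp_mat, 0))
  if (sum(mag) > 0) mag <- mag / sum(mag)
  pred <- fit$predictions$predicted_cr[match(rownames(x), fit$predictions$id)]
  sgn <- vapply(fit$features, function(col) {
    v <- x[[col]]
    if (stats::sd(v) == 0 || stats::sd(pred) == 0) return(1)
    s <- sign(stats::cor(v, pred))
    if (is.na(s) || s == 0) 1 else s
  }, numeric(1))
  out <- data.frame(feature = fit$features, importance = unname(mag),
                    sign = unname(sgn),
                    signed_importance = unname(mag * sgn),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  list(importance = out, top = utils::head(out, top_k))
}

#' Sex-stratified CR prediction and importance
#'
#' Fits two independent CR predictors, one on female-only and one on
#' male-only data, each with its own fold plan, and compares their top-k
#' signed importance lists.
#'
#' @param cohort An eligible cohort (supplies the sex of each id).
#' @param x Predictor matrix over the full cohort; the `sex_female` column
#'   is dropped within strata (it is constant there).
#' @param cr CR table from [compute_cr()].
#' @param assessment Assessment name.
#' @param k,seed Fold count and base seed (the male stratum uses `seed + 1`).
#' @param regressor Regressor specification.
#' @param top_k Size of the compared top lists.
#' @return A list: `female` and `male` (each with `fit` and `importance`),
#'   and `overlap` (features in both top-k lists).
#' @export
sex_stratified_importance <- function(cohort, x, cr, assessment, k = 5L,
                                      seed = 1L, regressor = regressor_rf(),
                                      top_k = 10L) {
  one_stratum <- function(sex_label, seed_offset) {
    ids <- cohort$id[cohort$sex == sex_label]
    if (length(ids) < k) {
      stop("stratum '", sex_label, "' has fewer individuals (", length(ids),
           ") than folds (", k, ")", call. = FALSE)
    }
    xs <- x[ids, setdiff(colnames(x), "sex_female"), drop = FALSE]
    crs <- cr[cr$id %in% ids, , drop = FALSE]
    fit <- fit_cr_predictor(xs, crs, assessment, k = k,
                            seed = seed + seed_offset, regressor = regressor)
    list(fit = fit, importance = rank_features(fit, xs, top_k = top_k))
  }
  female <- one_stratum("female", 0L)
  male <- one_stratum("male", 1L)
  list(female = female, male = male,
       overlap = intersect(female$importance$top$feature,
                           male$importance$top$feature))
}
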