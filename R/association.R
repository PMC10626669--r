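#' Cross-assessment correlation matrix
#'
#' Pearson (or Spearman) correlations between per-individual scores derived
#' from different cognitive assessments, e.g. CR scores or damage estimates.
#'
#' @param scores Long table with columns `id`, `assessment` and the value
#'   column named by `value`.
#' @param value Column to correlate (default `"cr_score"`; use `"damage"`
#'   for damage estimates).
#' @param method `"pearson"` or `"spearman"`.
#' @return A list: `r` (symmetric unit-diagonal matrix), `p` (two-sided
#'   p-values, NA on the diagonal), `n`.
#' @export
cross_assessment_matrix <- function(scores, value = "cr_score",
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  wide <- stats::reshape(
    scores[, c("id", "assessment", value)], direction = "wide",
    idvar = "id", timevar = "assessment")
  names(wide) <- sub(paste0("^", value, "\\."), "", names(wide))
  m <- as.matrix(wide[, setdiff(names(wide), "id"), drop = FALSE])
  if (nrow(m) < 3) stop("need at least 3 individuals", call. = FALSE)
  if (anyNA(m)) stop("score table is incomplete", call. = FALSE)
  k <- ncol(m)
  r <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- list(colnames(m), colnames(m))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ct <- stats::cor.test(m[, i], m[, j], method = method, exact = FALSE)
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(r = r, p = p, n = nrow(m))
}

#' Two-group comparison per assessment
#'
#' Welch (unequal-variance) t-test and Cohen's d with pooled standard
#' deviation, per assessment, for a binary grouping such as any-APOE-e4
#' versus none, female versus male, or NCI versus impaired. The sign
#' convention is `group1 - group2`.
#'
#' @param scores Long table (`id`, `assessment`, value column).
#' @param groups Data frame (`id`, `group`) with exactly two group labels.
#' @param value Value column (default `"cr_score"`).
#' @param group_order Optional length-2 character giving which label is
#'   group 1; default: sorted unique labels.
#' @return Data frame per assessment: group labels and sizes, means, mean
#'   difference, Cohen's d, Welch t, df and two-sided p-value.
#' @export
group_compare <- function(scores, groups, value = "cr_score",
                          group_order = NULL) {
  labs <- group_order %||% sort(unique(as.character(groups$group)))
  if (length(labs) != 2) stop("grouping must have exactly two labels", call. = FALSE)
  g <- as.character(groups$group[match(scores$id, groups$id)])
  if (anyNA(g)) stop("some scored ids have no group label", call. = FALSE)
  out <- lapply(split(seq_len(nrow(scores)), scores$assessment), function(rows) {
    v <- scores[[value]][rows]; gg <- g[rows]
    v1 <- v[gg == labs[1]]; v2 <- v[gg == labs[2]]
    if (length(v1) == 0 || length(v2) == 0) {
      stop("empty group '", labs[which(c(length(v1), length(v2)) == 0)[1]],
           "'", call. = FALSE)
    }
    tt <- stats::t.test(v1, v2, var.equal = FALSE)
    data.frame(assessment = scores$assessment[rows][1],
               group1 = labs[1], group2 = labs[2],
               n1 = length(v1), n2 = length(v2),
               mean1 = mean(v1), mean2 = mean(v2),
               mean_diff = mean(v1) - mean(v2),
               cohens_d = cohens_d(v1, v2),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Cohen's d with pooled standard deviation (n1+n2-2 denominator).
cohens_d <- function(v1, v2) {
  n1 <- length(v1); n2 <- length(v2)
  sp2 <- ((n1 - 1) * stats::var(v1) + (n2 - 1) * stats::var(v2)) / (n1 + n2 - 2)
  if (sp2 == 0) return(0)
  (mean(v1) - mean(v2)) / sqrt(sp2)
}

#' Correlation between scores and a per-individual covariate
#'
#' Per-assessment correlation between a score (CR or damage) and a numeric
#' covariate such as age at death (Pearson) or years of education
#' (Spearman).
#'
#' @param scores Long table (`id`, `assessment`, value column).
#' @param covariate Data frame (`id`, `value`).
#' @param value Score column (default `"cr_score"`).
#' @param method `"pearson"` or `"spearman"`.
#' @return Data frame per assessment: coefficient, two-sided p-value, n.
#' @export
covariate_correlation <- function(scores, covariate, value = "cr_score",
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  cv <- covariate$value[match(scores$id, covariate$id)]
  if (anyNA(cv)) stop("covariate missing for some scored ids", call. = FALSE)
  if (stats::sd(covariate$value) == 0) {
    stop("constant covariate: correlation undefined", call. = FALSE)
  }
  out <- lapply(split(seq_len(nrow(scores)), scores$assessment), function(rows) {
    ct <- stats::cor.test(scores[[value]][rows], cv[rows], method = method,
                          exact = FALSE)
    data.frame(assessment = scores$assessment[rows][1], method = method,
               estimate = unname(ct$estimate), p_value = ct$p.value,
               n = length(rows), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Covariate-adjusted linear model for CR scores
#'
#' Ordinary least squares of the CR score on age at death, sex, education,
#' APOE e4 count, cognitive status (ordinal 0/1/2 code) and a severity grade
#' of neuropathologic change, fit separately per assessment. Used to check
#' whether the sex effect on CR survives adjustment for plausible
#' confounders.
#'
#' @param cr CR table from [compute_cr()].
#' @param cohort The matching cohort.
#' @param adnc Data frame (`id`, `adnc`) with an ordinal severity grade of
#'   neuropathologic change (e.g. 0--3). If `NULL`, a 4-level grade is
#'   derived from quartiles of the cohort's normalized lesion-rank sum.
#' @return Data frame per assessment and term: estimate, standard error,
#'   t value, two-sided p-value.
#' @export
adjusted_linear_model <- function(cr, cohort, adnc = NULL) {
  if (is.null(adnc)) {
    schema <- cohort_schema(cohort)
    np <- as.matrix(as.data.frame(cohort)[, np_cols(schema), drop = FALSE])
    burden <- rowMeans(np)
    qs <- stats::quantile(burden, c(0.25, 0.5, 0.75), names = FALSE)
    adnc <- data.frame(id = cohort$id,
                       adnc = findInterval(burden, unique(qs)),
                       stringsAsFactors = FALSE)
  }
  covars <- data.frame(
    id = cohort$id,
    age_death = cohort$age_death,
    sex_female = as.numeric(cohort$sex == "female"),
    educ = cohort$educ,
    apoe_e4 = cohort$apoe_e4,
    status_code = as.numeric(status_to_code(cohort$status)),
    adnc = adnc$adnc[match(cohort$id, adnc$id)],
    stringsAsFactors = FALSE)
  out <- lapply(split(cr, cr$assessment), function(d) {
    dat <- merge(d[, c("id", "cr_score")], covars, by = "id")
    x <- stats::model.matrix(
      ~ age_death + sex_female + educ + apoe_e4 + status_code + adnc, dat)
    qr_x <- qr(x)
    if (qr_x$rank < ncol(x)) {
      dropped <- colnames(x)[qr_x$pivot[(qr_x$rank + 1):ncol(x)]]
      stop("rank-deficient design; collinear column(s): ",
           paste(dropped, collapse = ", "), call. = FALSE)
    }
    fit <- stats::lm(cr_score ~ age_death + sex_female + educ + apoe_e4 +
                       status_code + adnc, data = dat)
    sm <- summary(fit)$coefficients
    data.frame(assessment = d$assessment[1], term = rownames(sm),
               estimate = sm[, 1], std_error = sm[, 2],
               t = sm[, 3], p_value = sm[, 4],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Min-max normalization to the unit interval
#'
#' `(x - min) / (max - min)`; a constant vector maps to all zeros with a
#' warning. Used to put damage estimates from differently scaled assessments
#' on a common display scale.
#'
#' @param x Nonempty numeric vector without `NA`.
#' @return Numeric vector in \[0, 1\].
#' @export
minmax_normalize <- function(x) {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  if (anyNA(x)) stop("input contains NA", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant input; returning all zeros", call. = FALSE)
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}
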