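#' Solve for the continuous CR score
#'
#' The linear identity `cognitive measure = CR - damage` (all terms in the
#' same oriented units) is solved per individual and assessment:
#' `cr_score = measure + damage`. When damage is 0 the score reduces to the
#' reserve special case, `cr_score = measure`. The identity is exact by
#' construction and is asserted downstream, never approximated.
#'
#' @param measures Oriented measures from [orient_assessments()].
#' @param damage Long damage table from [estimate_damage()] (or
#'   [compute_damage()] rows bound together).
#' @return Long data frame: `id`, `assessment`, `measure`, `damage`,
#'   `cr_score`, plus the stored `actual_estimate`/`counterfactual_estimate`
#'   carried through for residual diagnostics.
#' @export
compute_cr <- function(measures, damage) {
  a_names <- setdiff(names(measures), "id")
  if (!all(damage$assessment %in% a_names)) {
    stop("damage table contains assessments without oriented measures: ",
         paste(setdiff(unique(damage$assessment), a_names), collapse = ", "),
         call. = FALSE)
  }
  if (!all(damage$id %in% measures$id)) {
    stop("damage table contains ids without oriented measures", call. = FALSE)
  }
  m_long <- stats::reshape(
    measures, direction = "long", varying = a_names, v.names = "measure",
    times = a_names, timevar = "assessment", idvar = "id")
  key_d <- paste(damage$id, damage$assessment)
  key_m <- paste(m_long$id, m_long$assessment)
  measure <- m_long$measure[match(key_d, key_m)]
  out <- data.frame(id = damage$id, assessment = damage$assessment,
                    measure = measure, damage = damage$damage,
                    cr_score = measure + damage$damage,
                    stringsAsFactors = FALSE)
  if (!is.null(damage$actual_estimate)) {
    out$actual_estimate <- damage$actual_estimate
    out$counterfactual_estimate <- damage$counterfactual_estimate
  }
  rownames(out) <- NULL
  out
}

#' Residual-based alternative resilience score
#'
#' The residual of the damage model -- oriented measure minus the out-of-fold
#' actual estimate -- is an alternative resilience proxy used by earlier
#' work. This returns the residuals alongside the CR score and reports their
#' per-assessment Pearson correlation, quantifying how closely the two
#' formulations agree. Algebraically, `cr_score - residual` equals the
#' counterfactual estimate for every cell.
#'
#' @param cr CR table from [compute_cr()] with stored actual estimates.
#' @return A list: `scores` (long data frame adding `residual`) and
#'   `comparison` (per-assessment Pearson r and two-sided p between residual
#'   and CR score).
#' @export
compute_residual_scores <- function(cr) {
  if (is.null(cr$actual_estimate)) {
    stop("cr table lacks stored actual estimates; rerun compute_cr() on ",
         "damage output that retains them", call. = FALSE)
  }
  scores <- cr
  scores$residual <- cr$measure - cr$actual_estimate
  comparison <- do.call(rbind, lapply(split(scores, scores$assessment), function(d) {
    ct <- stats::cor.test(d$residual, d$cr_score)
    data.frame(assessment = d$assessment[1], r = unname(ct$estimate),
               p_value = ct$p.value, n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(comparison) <- NULL
  list(scores = scores, comparison = comparison)
}

#' Label traditional binary resilience
#'
#' The traditional categorical notion of resilience: high neuropathologic
#' burden with no cognitive impairment. Used only for descriptive comparison
#' against the continuous CR score; by default "high burden" means a
#' composite lesion index at or above the cohort's 75th percentile.
#'
#' @param cohort An eligible cohort (complete lesion rankings).
#' @param np_index Function mapping the lesion-rank matrix to a composite
#'   burden index per individual. Default: normalized rank sum.
#' @param threshold Burden cutoff; default the 75th percentile of the
#'   cohort's composite index.
#' @return Data frame (`id`, `np_index`, `is_traditional_resilient`).
#' @export
label_traditional_resilience <- function(cohort,
                                         np_index = function(np) rowMeans(np),
                                         threshold = NULL) {
  schema <- cohort_schema(cohort)
  np <- as.matrix(as.data.frame(cohort)[, np_cols(schema), drop = FALSE])
  if (anyNA(np)) stop("lesion rankings must be complete", call. = FALSE)
  idx <- np_index(np)
  if (is.null(threshold)) threshold <- stats::quantile(idx, 0.75, names = FALSE)
  data.frame(id = cohort$id, np_index = idx,
             is_traditional_resilient = idx >= threshold & cohort$status == "NCI",
             stringsAsFactors = FALSE)
}
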