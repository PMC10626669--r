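#' Read and validate a cohort table
#'
#' Reads a delimited cohort file (comma-separated, header row, empty cell =
#' missing) with one row per autopsied individual: identifier, demographics,
#' APOE allele counts, consensus cognitive status, assessment-to-autopsy
#' interval, ordinal neuropathologic lesion rankings (`np_*` columns), raw
#' cognitive test scores (`test_*` columns) and optional intra-vitam medical
#' predictors (`med_*` columns).
#'
#' Validation enforces unique ids, known status labels, lesion ranks within
#' each feature's declared ordinal range and raw test scores within each
#' assessment's raw range. Missing cells are preserved as `NA` (filtered later
#' by [apply_eligibility()] or filled by [impute_np_means()]).
#'
#' @param path Path to the CSV file.
#' @param schema A [np_schema()]; default 17 features with 4 levels.
#' @param registry Assessment registry; default [default_registry()].
#'
#' @return A validated cohort `data.frame` (class `cr_cohort`) carrying the
#'   schema and registry as attributes.
#' @seealso [write_cohort()], [apply_eligibility()], [orient_assessments()]
#' @export
read_cohort <- function(path, schema = np_schema(), registry = default_registry()) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""),
                         check.names = FALSE)
  as_cohort(raw, schema = schema, registry = registry)
}

#' Construct a cohort from an in-memory data frame
#'
#' @param df Data frame in the same column layout as [read_cohort()] expects.
#' @inheritParams read_cohort
#' @return A validated cohort `data.frame` (class `cr_cohort`).
#' @export
as_cohort <- function(df, schema = np_schema(), registry = default_registry()) {
  required <- c("id", "sex", "age_death", "educ", "apoe_e4", "apoe_e2",
                "status", "interval_months", np_cols(schema), test_cols(registry))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    stop("cohort ids are not unique: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "), call. = FALSE)
  }
  bad_sex <- !is.na(df$sex) & !df$sex %in% c("female", "male")
  if (any(bad_sex)) {
    stop("invalid sex value(s) in row id ",
         paste(df$id[bad_sex], collapse = ", "), call. = FALSE)
  }
  bad_status <- !is.na(df$status) & !df$status %in% STATUS_LEVELS
  if (any(bad_status)) {
    stop("invalid cognitive status in row id ",
         paste(df$id[bad_status], collapse = ", "), call. = FALSE)
  }
  for (al in c("apoe_e4", "apoe_e2")) {
    bad <- !is.na(df[[al]]) & !df[[al]] %in% 0:2
    if (any(bad)) {
      stop(al, " allele count outside {0,1,2} in row id ",
           paste(df$id[bad], collapse = ", "), call. = FALSE)
    }
  }
  npc <- np_cols(schema)
  for (j in seq_along(npc)) {
    v <- df[[npc[j]]]
    top <- schema$levels_per_feature[j] - 1L
    bad <- !is.na(v) & (v < 0 | v > top)
    if (any(bad)) {
      stop("neuropathologic rank out of range [0, ", top, "] for ", npc[j],
           " in row id ", paste(df$id[bad], collapse = ", "), call. = FALSE)
    }
  }
  for (spec in registry) {
    if (spec$kind != "continuous") next
    col <- paste0("test_", spec$name)
    df[[col]] <- as.numeric(df[[col]])
    v <- df[[col]]
    bad <- !is.na(v) & (v < spec$raw_range[1] | v > spec$raw_range[2])
    if (any(bad)) {
      stop(spec$name, " raw score outside [", spec$raw_range[1], ", ",
           spec$raw_range[2], "] in row id ",
           paste(df$id[bad], collapse = ", "), call. = FALSE)
    }
  }
  rownames(df) <- NULL
  structure(df, np_schema = schema, registry = registry,
            class = c("cr_cohort", "data.frame"))
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: missing cells are written as empty strings so a
#' write/read round trip reproduces all non-missing cells exactly.
#'
#' @param cohort A cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

cohort_schema <- function(cohort) {
  attr(cohort, "np_schema") %||% np_schema()
}

cohort_registry <- function(cohort) {
  attr(cohort, "registry") %||% default_registry()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply the cohort eligibility criteria
#'
#' Retains exactly the individuals with (i) complete lesion rankings across
#' all neuropathologic features, (ii) complete results for all five cognitive
#' assessments (four tests plus the consensus diagnosis), and (iii) an
#' assessment-to-autopsy interval strictly below 24 months. Row order is
#' preserved and the operation is idempotent.
#'
#' @param cohort A validated cohort.
#' @param max_interval_months Exclusive upper bound on the interval (default 24).
#' @return The filtered cohort (possibly empty).
#' @export
apply_eligibility <- function(cohort, max_interval_months = 24) {
  schema <- cohort_schema(cohort)
  registry <- cohort_registry(cohort)
  npc <- np_cols(schema)
  tc <- test_cols(registry)
  np_complete <- if (length(npc)) stats::complete.cases(cohort[, npc, drop = FALSE]) else TRUE
  test_complete <- if (length(tc)) stats::complete.cases(cohort[, tc, drop = FALSE]) else TRUE
  has_diag <- if (any(vapply(registry, `[[`, character(1), "kind") == "ordinal_diagnosis")) {
    !is.na(cohort$status)
  } else TRUE
  keep <- np_complete & test_complete & has_diag &
    !is.na(cohort$interval_months) & cohort$interval_months < max_interval_months
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, np_schema = schema, registry = registry,
            class = c("cr_cohort", "data.frame"))
}

#' Mean-impute missing neuropathologic ranks
#'
#' Replaces every missing lesion rank by the unweighted mean of that feature's
#' non-missing values over the cohort, as used for expanded-cohort analyses
#' where incomplete autopsy panels would otherwise exclude most individuals.
#' Imputed ranks are deliberately left non-integer; the damage model consumes
#' them as numeric severity scores.
#'
#' @param cohort A validated cohort.
#' @return The cohort with a complete neuropathology block.
#' @export
impute_np_means <- function(cohort) {
  schema <- cohort_schema(cohort)
  for (col in np_cols(schema)) {
    v <- cohort[[col]]
    if (all(is.na(v))) {
      stop("cannot impute ", col, ": no observed values", call. = FALSE)
    }
    if (anyNA(v)) {
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      cohort[[col]] <- v
    }
  }
  cohort
}

#' Orient assessments so larger always means better cognition
#'
#' Converts raw assessment results to a common orientation: pass-through for
#' tests where higher raw scores are better, negation for timed tests
#' (TRAILB: longer completion time = worse), and the reversed ordinal code
#' for the consensus diagnosis (dementia = 0, MCI = 1, NCI = 2). Damage and
#' CR scores computed downstream are therefore sign-comparable across
#' assessments: larger damage always means more impairment and larger CR
#' always means more resilience.
#'
#' @param cohort An eligible cohort (no missing assessments; run
#'   [apply_eligibility()] first).
#' @param registry Assessment registry; defaults to the cohort's own.
#' @return A data frame of oriented measures: column `id` plus one numeric
#'   column per assessment.
#' @export
orient_assessments <- function(cohort, registry = cohort_registry(cohort)) {
  out <- data.frame(id = cohort$id, stringsAsFactors = FALSE)
  for (spec in registry) {
    if (spec$kind == "ordinal_diagnosis") {
      if (anyNA(cohort$status)) {
        stop("missing cognitive status; apply_eligibility() first", call. = FALSE)
      }
      out[[spec$name]] <- as.numeric(status_to_code(cohort$status))
    } else {
      col <- paste0("test_", spec$name)
      if (is.null(cohort[[col]])) {
        stop("unknown assessment column: ", col, call. = FALSE)
      }
      if (anyNA(cohort[[col]])) {
        stop("missing ", spec$name, " scores; apply_eligibility() first",
             call. = FALSE)
      }
      out[[spec$name]] <- if (spec$higher_is_better) {
        as.numeric(cohort[[col]])
      } else {
        -as.numeric(cohort[[col]])
      }
    }
  }
  out
}
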