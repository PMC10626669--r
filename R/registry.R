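#' Assessment specification
#'
#' Describes one cognitive assessment: its admissible raw range, whether a
#' larger raw score means better cognition, and whether it is a continuous
#' neuropsychological test or an ordinal consensus diagnosis.
#'
#' @param name Assessment identifier (e.g. `"ANIMALS"`).
#' @param raw_range Length-2 numeric, inclusive lower/upper bound of raw scores.
#' @param higher_is_better Logical; `FALSE` for timed tests where longer
#'   completion means worse performance.
#' @param kind `"continuous"` for neuropsychological tests,
#'   `"ordinal_diagnosis"` for the consensus cognitive-status category.
#'
#' @return An object of class `assessment_spec`.
#' @export
assessment_spec <- function(name, raw_range, higher_is_better, kind = "continuous") {
  stopifnot(is.character(name), length(name) == 1L)
  stopifnot(is.numeric(raw_range), length(raw_range) == 2L)
  if (raw_range[1] >= raw_range[2]) {
    stop("raw_range lower bound must be strictly below the upper bound", call. = FALSE)
  }
  kind <- match.arg(kind, c("continuous", "ordinal_diagnosis"))
  structure(
    list(name = name, raw_range = as.numeric(raw_range),
         higher_is_better = isTRUE(higher_is_better), kind = kind),
    class = "assessment_spec"
  )
}

#' @export
print.assessment_spec <- function(x, ...) {
  cat(sprintf("<assessment_spec> %s [%g, %g] %s (%s)\n",
              x$name, x$raw_range[1], x$raw_range[2],
              if (x$higher_is_better) "higher=better" else "higher=worse",
              x$kind))
  invisible(x)
}

#' Default registry of the five cognitive assessments
#'
#' Four neuropsychological tests -- semantic fluency (ANIMALS), story recall
#' (LOGIMEM), trail-making B completion time in seconds (TRAILB), digit-symbol
#' substitution (WAIS) -- plus the three-level consensus cognitive diagnosis
#' (NACCUDSD: no cognitive impairment / mild cognitive impairment / dementia),
#' used as a fifth, ordinal assessment. TRAILB is the only test where a larger
#' raw value means worse cognition; NACCUDSD raw codes are 0 = dementia,
#' 1 = MCI, 2 = NCI so that larger is better.
#'
#' @return Named list of [assessment_spec()] objects.
#' @export
default_registry <- function() {
  specs <- list(
    assessment_spec("ANIMALS",  c(0, 77),  higher_is_better = TRUE),
    assessment_spec("LOGIMEM",  c(0, 25),  higher_is_better = TRUE),
    assessment_spec("TRAILB",   c(0, 300), higher_is_better = FALSE),
    assessment_spec("WAIS",     c(0, 93),  higher_is_better = TRUE),
    assessment_spec("NACCUDSD", c(0, 2),   higher_is_better = TRUE,
                    kind = "ordinal_diagnosis")
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Ordinal neuropathology schema
#'
#' Declares the ordinal lesion-ranking features available for damage
#' estimation. Ranks are consecutive integers starting at 0 (no/lowest lesion
#' burden). The default mirrors a comprehensive autopsy panel of 17 features,
#' each on a 4-level scale; both counts are configurable for testing.
#'
#' @param n_features Number of ordinal features (default 17).
#' @param levels Integer scalar or vector of per-feature ordinal level counts
#'   (each >= 2; default 4, i.e. ranks 0--3).
#' @param feature_names Optional feature identifiers; default `npf01..npf17`.
#'
#' @return An object of class `np_schema` with elements `feature_names` and
#'   `levels_per_feature`.
#' @export
np_schema <- function(n_features = 17L, levels = 4L, feature_names = NULL) {
  n_features <- as.integer(n_features)
  stopifnot(n_features >= 1L)
  levels <- as.integer(levels)
  if (length(levels) == 1L) levels <- rep(levels, n_features)
  if (length(levels) != n_features || any(levels < 2L)) {
    stop("levels must be a scalar or length n_features, all >= 2", call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- sprintf("npf%02d", seq_len(n_features))
  }
  stopifnot(length(feature_names) == n_features, !anyDuplicated(feature_names))
  structure(
    list(feature_names = feature_names, levels_per_feature = levels),
    class = "np_schema"
  )
}

#' @export
print.np_schema <- function(x, ...) {
  cat(sprintf("<np_schema> %d ordinal features, levels %s\n",
              length(x$feature_names),
              paste(unique(x$levels_per_feature), collapse = "/")))
  invisible(x)
}

# Internal: registry/schema-derived column names in the cohort table.
np_cols <- function(schema) paste0("np_", schema$feature_names)

test_cols <- function(registry) {
  cont <- Filter(function(s) s$kind == "continuous", registry)
  paste0("test_", vapply(cont, `[[`, character(1), "name"))
}

assessment_names <- function(registry) {
  vapply(registry, `[[`, character(1), "name")
}

# Ordinal diagnosis coding shared across the package: larger = better cognition.
STATUS_LEVELS <- c("dementia", "MCI", "NCI")

status_to_code <- function(status) {
  code <- match(status, STATUS_LEVELS) - 1L
  if (anyNA(code) && !anyNA(status)) {
    bad <- unique(status[is.na(code) & !is.na(status)])
    stop("unknown cognitive status value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  code
}

code_to_status <- function(code) STATUS_LEVELS[as.integer(code) + 1L]
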