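#' Phenotype algorithm configuration
#'
#' Thresholds, temporal windows, and code sets for the type 2 diabetes
#' case/control definitions. Defaults follow the ADA laboratory criteria
#' (HbA1c >= 6.5 percent, fasting glucose >= 126 mg/dL, random glucose
#' >= 200 mg/dL) and the study's temporal constraints: the second abnormal
#' lab and a normal lab must fall within three years (1095 d) before the
#' first type 2 code, the first type 2 code must precede any type 1 code
#' by at least one year (365 d), antidiabetic treatment more than 30 days
#' before onset excludes, and subjects must be at least 30 years old by
#' the end of the study window (1995-01-01 to 2009-12-31).
#'
#' @param hba1c_threshold Percent; abnormal at or above.
#' @param fasting_threshold,random_threshold mg/dL; abnormal at or above.
#' @param onset_window Days; the "three years" lab window (default 1095).
#' @param type1_precedence Days a type 1 code must trail the first type 2
#'   code (default 365).
#' @param med_exclusion_lead Days of antidiabetic treatment before the
#'   anchor date that trigger exclusion (default 30).
#' @param min_age_years Minimum completed age at the study-window end.
#' @param study_start,study_end Incidence accrual window.
#' @param code_sets Named list of [code_set()]s; must contain `type2`,
#'   `type1`, `diabetes_related`.
#' @param med_anchor `"onset"` (default) anchors the medication exclusion
#'   at the assigned onset date; `"code"` at the first type 2 code date.
#' @param exclude_probable_undiagnosed If `TRUE`, controls with two or
#'   more abnormal labs on distinct dates are excluded (sensitivity
#'   analysis; off by default — the base definition does not exclude
#'   controls for abnormal labs).
#' @return Object of class `phenotype_config`.
#' @export
phenotype_config <- function(hba1c_threshold = 6.5,
                             fasting_threshold = 126,
                             random_threshold = 200,
                             onset_window = 1095,
                             type1_precedence = 365,
                             med_exclusion_lead = 30,
                             min_age_years = 30,
                             study_start = as.Date("1995-01-01"),
                             study_end = as.Date("2009-12-31"),
                             code_sets = default_code_sets(),
                             med_anchor = c("onset", "code"),
                             exclude_probable_undiagnosed = FALSE) {
  med_anchor <- match.arg(med_anchor)
  num <- c(hba1c_threshold, fasting_threshold, random_threshold,
           onset_window, type1_precedence, med_exclusion_lead, min_age_years)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stopf("all thresholds and windows must be strictly positive")
  }
  for (nm in c("type2", "type1", "diabetes_related")) {
    if (!inherits(code_sets[[nm]], "code_set")) stopf("code_sets must contain '%s'", nm)
  }
  structure(list(
    hba1c_threshold = hba1c_threshold, fasting_threshold = fasting_threshold,
    random_threshold = random_threshold, onset_window = as.integer(onset_window),
    type1_precedence = as.integer(type1_precedence),
    med_exclusion_lead = as.integer(med_exclusion_lead),
    min_age_years = as.integer(min_age_years),
    study_start = as_emr_date(study_start), study_end = as_emr_date(study_end),
    code_sets = code_sets, med_anchor = med_anchor,
    exclude_probable_undiagnosed = exclude_probable_undiagnosed
  ), class = "phenotype_config")
}

#' Full pipeline run configuration
#'
#' Wraps a [phenotype_config()] with the cohort-construction settings:
#' the target control:case matching ratio (5), birth-category cut points
#' (`NULL` = compute quintiles of the case birth-year distribution at run
#' time and freeze them into the result), follow-up end (2011-12-31), the
#' minimum post-reference observation requirement (60 d), the engagement
#' look-back (3 calendar years strictly prior to the reference year), and
#' the global seed.
#'
#' @param phenotype A [phenotype_config()].
#' @param ratio Target controls per case.
#' @param birth_cuts Integer vector of 4 interior birth-year cut points,
#'   or `NULL` to derive quintiles from the cases.
#' @param followup_end Last follow-up date.
#' @param min_observation_days Minimum days from reference date to the
#'   censored follow-up end.
#' @param engagement_years Calendar years before the reference year in
#'   which a non-diabetes diagnosis or well-visit is required.
#' @param engagement_include_reference_year Count the reference year
#'   itself toward engagement (default `FALSE`, the strict reading).
#' @param gap_years Consecutive encounter-free calendar years that define
#'   an EMR gap (default 4).
#' @param seed Global seed; all stochastic stages derive named substreams
#'   from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(phenotype = phenotype_config(),
                       ratio = 5,
                       birth_cuts = NULL,
                       followup_end = as.Date("2011-12-31"),
                       min_observation_days = 60,
                       engagement_years = 3,
                       engagement_include_reference_year = FALSE,
                       gap_years = 4,
                       seed = 1L) {
  stopifnot(inherits(phenotype, "phenotype_config"), ratio >= 1)
  if (!is.null(birth_cuts) && length(birth_cuts) != 4) {
    stopf("birth_cuts must be NULL or exactly 4 interior cut points")
  }
  structure(list(
    phenotype = phenotype, ratio = ratio, birth_cuts = birth_cuts,
    followup_end = as_emr_date(followup_end),
    min_observation_days = as.integer(min_observation_days),
    engagement_years = as.integer(engagement_years),
    engagement_include_reference_year = engagement_include_reference_year,
    gap_years = as.integer(gap_years), seed = as.integer(seed)
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Every field is optional; anything absent takes the package default, so
#' an empty file yields `run_config()`. Code sets may be overridden under
#' a `code_sets:` key with the wildcard syntax of [code_set()]. Use
#' [config_as_list()] to echo the fully defaulted configuration back out
#' (written into every run manifest).
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  cs <- default_code_sets()
  for (nm in names(raw$code_sets %||% list())) {
    cs[[nm]] <- code_set(nm, unlist(raw$code_sets[[nm]]))
  }
  ph <- raw$phenotype %||% list()
  pc <- phenotype_config(
    hba1c_threshold = ph$hba1c_threshold %||% 6.5,
    fasting_threshold = ph$fasting_threshold %||% 126,
    random_threshold = ph$random_threshold %||% 200,
    onset_window = ph$onset_window %||% 1095,
    type1_precedence = ph$type1_precedence %||% 365,
    med_exclusion_lead = ph$med_exclusion_lead %||% 30,
    min_age_years = ph$min_age_years %||% 30,
    study_start = as.Date(ph$study_start %||% "1995-01-01"),
    study_end = as.Date(ph$study_end %||% "2009-12-31"),
    code_sets = cs,
    med_anchor = ph$med_anchor %||% "onset",
    exclude_probable_undiagnosed = isTRUE(ph$exclude_probable_undiagnosed)
  )
  mt <- raw$matching %||% list()
  run_config(
    phenotype = pc,
    ratio = mt$ratio %||% 5,
    birth_cuts = mt$birth_cuts,
    followup_end = as.Date(raw$followup_end %||% "2011-12-31"),
    min_observation_days = mt$min_observation_days %||% 60,
    engagement_years = mt$engagement_years %||% 3,
    engagement_include_reference_year = isTRUE(mt$engagement_include_reference_year),
    gap_years = mt$gap_years %||% 4,
    seed = raw$seed %||% 1L
  )
}

#' Serialize a run configuration to a plain list
#'
#' The echo-back used in run manifests: every default is materialized, so
#' the list is a superset of any YAML the config was loaded from.
#'
#' @param config A [run_config()].
#' @return Nested list suitable for `yaml::write_yaml()`.
#' @export
config_as_list <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pc <- config$phenotype
  list(
    phenotype = list(
      hba1c_threshold = pc$hba1c_threshold,
      fasting_threshold = pc$fasting_threshold,
      random_threshold = pc$random_threshold,
      onset_window = pc$onset_window,
      type1_precedence = pc$type1_precedence,
      med_exclusion_lead = pc$med_exclusion_lead,
      min_age_years = pc$min_age_years,
      study_start = as.character(pc$study_start),
      study_end = as.character(pc$study_end),
      med_anchor = pc$med_anchor,
      exclude_probable_undiagnosed = pc$exclude_probable_undiagnosed
    ),
    matching = list(
      ratio = config$ratio,
      birth_cuts = config$birth_cuts,
      min_observation_days = config$min_observation_days,
      engagement_years = config$engagement_years,
      engagement_include_reference_year = config$engagement_include_reference_year,
      gap_years = config$gap_years
    ),
    followup_end = as.character(config$followup_end),
    seed = config$seed,
    code_sets = lapply(pc$code_sets, function(s) s$patterns)
  )
}
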