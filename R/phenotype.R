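#' Classify a glycemic laboratory result
#'
#' Applies the configured ADA-style thresholds: a result is `abnormal`
#' when its value is at or above the analyte's threshold (the threshold
#' value itself is abnormal), `normal` otherwise.
#'
#' @param analyte Character vector: `"hba1c"`, `"fasting_glucose"` or
#'   `"random_glucose"`.
#' @param value Numeric vector (percent for HbA1c, mg/dL for glucose).
#' @param config A [phenotype_config()].
#' @return data.frame with columns `analyte`, `value`, `threshold_used`,
#'   `label` (`"normal"`/`"abnormal"`).
#' @examples
#' cfg <- phenotype_config()
#' classify_lab("hba1c", c(6.5, 6.49), cfg)$label  # "abnormal" "normal"
#' @export
classify_lab <- function(analyte, value, config) {
  stopifnot(inherits(config, "phenotype_config"))
  if (any(!analyte %in% VALID_ANALYTES)) {
    stopf("unknown analyte: %s",
          paste(setdiff(unique(analyte), VALID_ANALYTES), collapse = ", "))
  }
  thr <- lab_thresholds(config)[analyte]
  data.frame(analyte = analyte, value = value, threshold_used = unname(thr),
             label = ifelse(value >= thr, "abnormal", "normal"))
}

lab_thresholds <- function(config) {
  c(hba1c = config$hba1c_threshold,
    fasting_glucose = config$fasting_threshold,
    random_glucose = config$random_threshold)
}

lab_is_abnormal <- function(analyte, value, config) {
  value >= lab_thresholds(config)[analyte]
}

#' First type 2 diabetes code date within the study window
#'
#' @param diagnoses data.frame with `date` and `code` for one patient.
#' @param config A [phenotype_config()].
#' @return The earliest matching `Date`, or `NA` if none.
#' @export
first_type2_code_date <- function(diagnoses, config) {
  stopifnot(inherits(config, "phenotype_config"))
  if (nrow(diagnoses) == 0) return(as.Date(NA))
  hit <- code_matches(diagnoses$code, config$code_sets$type2) &
    diagnoses$date >= config$study_start & diagnoses$date <= config$study_end
  if (!any(hit)) return(as.Date(NA))
  min(diagnoses$date[hit])
}

#' Assign the date of diabetes onset
#'
#' The onset date is the earlier of the first type 2 diagnostic code and
#' the chronologically second abnormal glycemic laboratory result; ties
#' return the shared date.
#'
#' @param first_code_date,second_abnormal_date `Date` scalars, both
#'   required (the case criteria guarantee both exist).
#' @return `Date` scalar.
#' @export
assign_onset_date <- function(first_code_date, second_abnormal_date) {
  if (is.na(first_code_date) || is.na(second_abnormal_date)) {
    stopf("assign_onset_date requires both dates; case criteria not satisfied")
  }
  min(first_code_date, second_abnormal_date)
}

# Reason codes, in the fixed order they are evaluated. Every failed
# criterion is recorded (not just the first), so attrition tallies under
# alternative groupings stay reproducible.
REASONS_ELIGIBILITY <- c("age_below_minimum", "prestudy_diabetes_related_code",
                         "prestudy_diabetes_medication")
REASONS_CASE <- c("type1_within_precedence", "abnormal_lab_gt_3y_before_code",
                  "insufficient_abnormal_labs", "no_normal_lab_within_3y",
                  "med_before_onset")
REASONS_CONTROL <- c("diabetes_related_code", "no_normal_lab",
                     "diabetes_medication", "probable_undiagnosed_diabetes")

# Core per-patient decision on pre-extracted vectors. dx_* are logical
# code-set matches aligned with dx_date; lab_abn aligned with lab_date;
# med_anti marks antidiabetic classes aligned with med_start.
decide_patient <- function(patient_id, birth_date,
                           dx_date, dx_t2, dx_t1, dx_rel,
                           lab_date, lab_abn,
                           med_start, med_anti, config) {
  decision <- function(status, reasons, onset = as.Date(NA),
                       first_code = as.Date(NA), second_abn = as.Date(NA)) {
    list(patient_id = patient_id, status = status, onset_date = onset,
         first_t2d_code_date = first_code, second_abnormal_date = second_abn,
         reasons = reasons)
  }

  reasons <- character()
  if (age_completed_years(birth_date, config$study_end) < config$min_age_years) {
    reasons <- c(reasons, "age_below_minimum")
  }
  if (any(dx_rel & dx_date < config$study_start)) {
    reasons <- c(reasons, "prestudy_diabetes_related_code")
  }
  if (any(med_anti & med_start < config$study_start)) {
    reasons <- c(reasons, "prestudy_diabetes_medication")
  }
  if (length(reasons) > 0) return(decision("ineligible", reasons))

  in_window <- dx_t2 & dx_date >= config$study_start & dx_date <= config$study_end
  if (!any(in_window)) {
    # control path
    n_events <- length(dx_date) + length(lab_date) + length(med_start)
    if (n_events == 0) return(decision("ineligible", "no_normal_lab"))
    if (any(dx_rel & dx_date <= config$study_end)) {
      reasons <- c(reasons, "diabetes_related_code")
    }
    if (!any(!lab_abn & lab_date <= config$study_end)) {
      reasons <- c(reasons, "no_normal_lab")
    }
    if (any(med_anti & med_start <= config$study_end)) {
      reasons <- c(reasons, "diabetes_medication")
    }
    if (config$exclude_probable_undiagnosed &&
        length(unique(lab_date[lab_abn & lab_date <= config$study_end])) >= 2) {
      reasons <- c(reasons, "probable_undiagnosed_diabetes")
    }
    status <- if (length(reasons) == 0) "control" else "excluded"
    return(decision(status, reasons))
  }

  first_code <- min(dx_date[in_window])
  if (any(dx_t1 & dx_date <= first_code + config$type1_precedence)) {
    reasons <- c(reasons, "type1_within_precedence")
  }
  abn_dates <- sort(unique(lab_date[lab_abn]))   # same-day duplicates count once
  if (any(abn_dates < first_code - config$onset_window)) {
    reasons <- c(reasons, "abnormal_lab_gt_3y_before_code")
  }
  second_abn <- if (length(abn_dates) >= 2) abn_dates[2] else as.Date(NA)
  if (is.na(second_abn) || second_abn < first_code - config$onset_window) {
    reasons <- c(reasons, "insufficient_abnormal_labs")
  }
  has_normal <- any(!lab_abn &
                      lab_date >= first_code - config$onset_window &
                      lab_date < first_code)
  if (!has_normal) reasons <- c(reasons, "no_normal_lab_within_3y")
  anchor <- if (config$med_anchor == "onset" && !is.na(second_abn)) {
    min(first_code, second_abn)
  } else first_code
  if (any(med_anti & med_start < anchor - config$med_exclusion_lead)) {
    reasons <- c(reasons, "med_before_onset")
  }
  if (length(reasons) == 0) {
    decision("case", character(),
             onset = assign_onset_date(first_code, second_abn),
             first_code = first_code, second_abn = second_abn)
  } else {
    decision("excluded", reasons, first_code = first_code, second_abn = second_abn)
  }
}

extract_patient_inputs <- function(patient, diagnoses, labs, medications, config) {
  diagnoses <- as.data.frame(diagnoses)
  labs <- as.data.frame(labs)
  medications <- as.data.frame(medications)
  list(
    dx_date = as_emr_date(diagnoses$date %||% as.Date(character())),
    dx_t2 = if (nrow(diagnoses)) code_matches(diagnoses$code, config$code_sets$type2) else logical(),
    dx_t1 = if (nrow(diagnoses)) code_matches(diagnoses$code, config$code_sets$type1) else logical(),
    dx_rel = if (nrow(diagnoses)) code_matches(diagnoses$code, config$code_sets$diabetes_related) else logical(),
    lab_date = as_emr_date(labs$date %||% as.Date(character())),
    lab_abn = if (nrow(labs)) lab_is_abnormal(labs$analyte, labs$value, config) else logical(),
    med_start = as_emr_date(medications$start_date %||% as.Date(character())),
    med_anti = if (nrow(medications)) medications$drug_class != "non_diabetes" else logical()
  )
}

#' Evaluate the type 2 diabetes case definition for one patient
#'
#' Applies, in fixed order: (1) eligibility (age, no pre-study
#' diabetes-related diagnoses or antidiabetic medication); (2) at least
#' one type 2 code in the study window, otherwise the patient is routed
#' to the control definition; (3) type 1 precedence; (4) no abnormal lab
#' more than `onset_window` days before the first code; (5) at least two
#' abnormal labs on distinct dates with the second inside the window;
#' (6) at least one normal lab within the window before the first code;
#' (7) onset assignment; (8) no antidiabetic medication starting more
#' than `med_exclusion_lead` days before the anchor date. Every failed
#' criterion is recorded as a reason; failures are decisions, not errors.
#'
#' @param patient One-row data.frame (or list) with `patient_id` and
#'   `birth_date`.
#' @param diagnoses,labs,medications This patient's event streams (may
#'   have zero rows), with the columns documented at [emr_dataset()].
#' @param config A [phenotype_config()].
#' @return Object of class `case_decision`: a list with `patient_id`,
#'   `status` (`case`/`control`/`excluded`/`ineligible`), `onset_date`,
#'   `first_t2d_code_date`, `second_abnormal_date`, `reasons`.
#' @export
evaluate_case <- function(patient, diagnoses, labs, medications, config) {
  stopifnot(inherits(config, "phenotype_config"))
  inp <- extract_patient_inputs(patient, diagnoses, labs, medications, config)
  d <- decide_patient(patient$patient_id, as_emr_date(patient$birth_date),
                      inp$dx_date, inp$dx_t2, inp$dx_t1, inp$dx_rel,
                      inp$lab_date, inp$lab_abn, inp$med_start, inp$med_anti,
                      config)
  structure(d, class = "case_decision")
}

#' Evaluate the control (no-diabetes) definition for one patient
#'
#' Controls must be age-eligible, have no diabetes-related diagnosis
#' through the study end, at least one normal glycemic lab, and no
#' antidiabetic medication through the study end. Callers should ensure
#' the patient has no type 2 code in the study window (the precondition);
#' if one is present the case path is evaluated instead.
#'
#' @inheritParams evaluate_case
#' @return A `case_decision` (see [evaluate_case()]).
#' @export
evaluate_control <- function(patient, diagnoses, labs, medications, config) {
  evaluate_case(patient, diagnoses, labs, medications, config)
}

#' @export
print.case_decision <- function(x, ...) {
  cat(sprintf("<case_decision %s> status=%s onset=%s reasons=[%s]\n",
              x$patient_id, x$status,
              ifelse(is.na(x$onset_date), "-", as.character(x$onset_date)),
              paste(x$reasons, collapse = ";")))
  invisible(x)
}

#' Run the phenotype over every patient in a dataset
#'
#' Each patient receives exactly one decision; the four statuses
#' partition the population. Code-set matching and lab classification are
#' vectorized over the whole dataset before the per-patient temporal
#' logic runs.
#'
#' @param dataset An [emr_dataset()].
#' @param config A [phenotype_config()].
#' @return data.frame (one row per patient): `patient_id`, `status`,
#'   `onset_date`, `first_t2d_code_date`, `second_abnormal_date`,
#'   `reasons` (semicolon-joined).
#' @export
evaluate_population <- function(dataset, config = phenotype_config()) {
  stopifnot(inherits(dataset, "emr_dataset"), inherits(config, "phenotype_config"))
  pats <- dataset$patients
  pid_levels <- pats$patient_id

  dx <- dataset$diagnoses
  dx_t2 <- code_matches(dx$code, config$code_sets$type2)
  dx_t1 <- code_matches(dx$code, config$code_sets$type1)
  dx_rel <- code_matches(dx$code, config$code_sets$diabetes_related)
  lb <- dataset$labs
  lab_abn <- if (nrow(lb)) lab_is_abnormal(lb$analyte, lb$value, config) else logical()
  md <- dataset$medications
  med_anti <- if (nrow(md)) md$drug_class != "non_diabetes" else logical()

  idx_dx <- split(seq_len(nrow(dx)), factor(dx$patient_id, levels = pid_levels))
  idx_lb <- split(seq_len(nrow(lb)), factor(lb$patient_id, levels = pid_levels))
  idx_md <- split(seq_len(nrow(md)), factor(md$patient_id, levels = pid_levels))

  n <- nrow(pats)
  status <- character(n)
  onset <- first_code <- second_abn <- rep(as.Date(NA), n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    ii <- idx_dx[[i]]; jj <- idx_lb[[i]]; kk <- idx_md[[i]]
    d <- decide_patient(pid_levels[i], pats$birth_date[i],
                        dx$date[ii], dx_t2[ii], dx_t1[ii], dx_rel[ii],
                        lb$date[jj], lab_abn[jj],
                        md$start_date[kk], med_anti[kk], config)
    status[i] <- d$status
    onset[i] <- d$onset_date
    first_code[i] <- d$first_t2d_code_date
    second_abn[i] <- d$second_abnormal_date
    reasons[i] <- paste(d$reasons, collapse = ";")
  }
  data.frame(patient_id = pid_levels, status = status, onset_date = onset,
             first_t2d_code_date = first_code, second_abnormal_date = second_abn,
             reasons = reasons, stringsAsFactors = FALSE)
}

#' Write the per-patient decision log
#'
#' @param decisions As returned by [evaluate_population()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_decisions <- function(decisions, path) {
  data.table::fwrite(decisions, path, dateTimeAs = "ISO")
  invisible(path)
}
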