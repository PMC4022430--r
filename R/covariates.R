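#' Cancer ascertainment by the two-code rule
#'
#' A site is positive when at least two diagnosis events match its code
#' set inside the observation window (`lookback_start` through
#' `followup_end`, inclusive); the diagnosis date is the first matching
#' event's date. A minimum separation between the two codes can be
#' required via `min_separation_days` (default 0: none).
#'
#' @param diagnoses One patient's diagnosis events (`date`, `code`).
#' @param site_code_sets Named list of [code_set()]s, one per site.
#' @param window An `observation_window` (see [censored_window()]).
#' @param min_separation_days Minimum days between the first and last
#'   qualifying code.
#' @return data.frame with one row per positive site: `site`,
#'   `diagnosis_date`, `n_codes`.
#' @export
ascertain_cancer <- function(diagnoses, site_code_sets, window,
                             min_separation_days = 0) {
  out <- list()
  dates <- as_emr_date(diagnoses$date)
  in_win <- dates >= window$lookback_start & dates <= window$followup_end
  for (site in names(site_code_sets)) {
    hit <- in_win & code_matches(diagnoses$code, site_code_sets[[site]])
    d <- sort(dates[hit])
    if (length(d) >= 2 && as.numeric(max(d) - min(d)) >= min_separation_days) {
      out[[site]] <- data.frame(site = site, diagnosis_date = d[1],
                                n_codes = length(d))
    }
  }
  if (length(out) == 0) {
    return(data.frame(site = character(), diagnosis_date = as.Date(character()),
                      n_codes = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default modified-Charlson weights
#'
#' Original Charlson (1987) weights for the seven retained conditions;
#' the diabetes and malignancy components are excluded by construction.
#' @return Named numeric vector.
#' @export
charlson_weights <- function() {
  c(myocardial_infarction = 1, coronary_heart_disease = 1,
    peripheral_vascular = 1, cardiovascular_disease = 1,
    chronic_pulmonary = 1, rheumatic_heart = 1, renal_disease = 2)
}

#' Comorbidity flags and modified Charlson score
#'
#' Each condition flag requires at least two matching diagnosis events
#' inside the observation window; the modified Charlson score is the sum
#' of the configured weights over flagged conditions (cancer and
#' diabetes components excluded).
#'
#' @param diagnoses One patient's diagnosis events.
#' @param window An `observation_window`.
#' @param comorbidity_code_sets Named list of [code_set()]s covering the
#'   conditions in `weights`.
#' @param weights Named numeric vector, as [charlson_weights()].
#' @return List: one logical flag per condition plus `charlson_modified`.
#' @export
comorbidity_profile <- function(diagnoses, window,
                                comorbidity_code_sets, weights = charlson_weights()) {
  miss <- setdiff(names(weights), names(comorbidity_code_sets))
  if (length(miss) > 0) stopf("no code set for condition(s): %s", paste(miss, collapse = ", "))
  dates <- as_emr_date(diagnoses$date)
  in_win <- dates >= window$lookback_start & dates <= window$followup_end
  flags <- vapply(names(weights), function(cond) {
    sum(in_win & code_matches(diagnoses$code, comorbidity_code_sets[[cond]])) >= 2
  }, logical(1))
  c(as.list(flags), list(charlson_modified = sum(weights[flags])))
}

VISIT_BINS <- c("0-5", "6-10", "11-20", ">20")

bin_visits <- function(n) VISIT_BINS[findInterval(n, c(0, 6, 11, 21))]

#' Visit frequency in the two years around the reference date
#'
#' Encounters are counted in the half-open windows `[ref - 730 d, ref)`
#' (pre) and `[ref, ref + 730 d)` (post) — an encounter exactly on the
#' reference date counts as "after" — and binned as 0-5, 6-10, 11-20,
#' >20.
#'
#' @param encounters One patient's encounters (`date`), or a `Date`
#'   vector.
#' @param reference_date Reference date.
#' @param window_days Width of each window in days (default 730).
#' @return List: `pre_n`, `pre_bin`, `post_n`, `post_bin`.
#' @export
visit_frequency <- function(encounters, reference_date, window_days = 730) {
  dates <- if (inherits(encounters, "Date")) encounters else as_emr_date(encounters$date)
  ref <- as_emr_date(reference_date)
  pre <- sum(dates >= ref - window_days & dates < ref)
  post <- sum(dates >= ref & dates < ref + window_days)
  list(pre_n = pre, pre_bin = bin_visits(pre),
       post_n = post, post_bin = bin_visits(post))
}

merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  total <- 0
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      total <- total + as.numeric(me - ms)
      ms <- start[i]; me <- end[i]
    }
  }
  total + as.numeric(me - ms)
}

#' Antidiabetic medication exposure within a window
#'
#' For each of insulin, metformin, sulfonylurea and other antidiabetic
#' classes: whether any record overlaps the observation window, the
#' first start date, and the total exposed days (union of the class's
#' intervals clipped to the window; open-ended records are truncated at
#' the window's follow-up end). Intended for the diabetes arm — controls
#' have no antidiabetic exposure by definition.
#'
#' @param medications One patient's medication records (`drug_class`,
#'   `start_date`, `stop_date`).
#' @param window An `observation_window`.
#' @return data.frame: `drug_class`, `ever`, `first_date`, `days_exposed`.
#' @export
medication_exposure <- function(medications, window) {
  classes <- setdiff(VALID_DRUG_CLASSES, "non_diabetes")
  res <- lapply(classes, function(cl) {
    m <- medications[medications$drug_class == cl, , drop = FALSE]
    if (nrow(m) == 0) {
      return(data.frame(drug_class = cl, ever = FALSE,
                        first_date = as.Date(NA), days_exposed = 0))
    }
    start <- as_emr_date(m$start_date)
    stop <- as_emr_date(m$stop_date)
    stop[is.na(stop)] <- window$followup_end
    cs <- pmax(start, window$lookback_start)
    ce <- pmin(stop, window$followup_end)
    ok <- cs <= ce
    if (!any(ok)) {
      return(data.frame(drug_class = cl, ever = FALSE,
                        first_date = as.Date(NA), days_exposed = 0))
    }
    data.frame(drug_class = cl, ever = TRUE, first_date = min(start[ok]),
               days_exposed = merge_intervals(cs[ok], ce[ok]))
  })
  do.call(rbind, res)
}

#' Per-member covariates and outcomes on censored windows
#'
#' Computes, for every cohort row and strictly within its observation
#' window: cancer diagnoses (two-code rule, three sites), the seven
#' comorbidity flags and modified Charlson score, pre/post visit
#' frequency bins, BMI nearest the reference date (within +/- 365 days),
#' insurance, and (diabetes arm) medication exposure.
#'
#' @param dataset An [emr_dataset()].
#' @param cohort The `cohort` data.frame from [build_cohort()].
#' @param config A [run_config()].
#' @return data.frame keyed by `patient_id`.
#' @export
compute_covariates <- function(dataset, cohort, config = run_config()) {
  cs <- config$phenotype$code_sets
  sites <- list(breast = cs$breast_cancer, prostate = cs$prostate_cancer,
                colon = cs$colon_cancer)
  weights <- charlson_weights()
  pats <- dataset$patients
  row_of <- stats::setNames(seq_len(nrow(pats)), pats$patient_id)
  dx_idx <- split(seq_len(nrow(dataset$diagnoses)),
                  factor(dataset$diagnoses$patient_id, levels = pats$patient_id))
  enc_idx <- split(seq_len(nrow(dataset$encounters)),
                   factor(dataset$encounters$patient_id, levels = pats$patient_id))
  md_idx <- split(seq_len(nrow(dataset$medications)),
                  factor(dataset$medications$patient_id, levels = pats$patient_id))
  bmi_idx <- split(seq_len(nrow(dataset$bmi)),
                   factor(dataset$bmi$patient_id, levels = pats$patient_id))

  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[i]
    r <- row_of[[pid]]
    win <- structure(list(lookback_start = cohort$lookback_start[i],
                          reference_date = cohort$reference_date[i],
                          followup_end = cohort$followup_end[i]),
                     class = "observation_window")
    dxp <- dataset$diagnoses[dx_idx[[r]]]
    ca <- ascertain_cancer(dxp, sites, win)
    com <- comorbidity_profile(dxp, win, cs, weights)
    vf <- visit_frequency(dataset$encounters$date[enc_idx[[r]]], win$reference_date)
    bmip <- dataset$bmi[bmi_idx[[r]]]
    bmi_ref <- NA_real_
    if (nrow(bmip) > 0) {
      dist <- abs(as.numeric(bmip$date - win$reference_date))
      j <- which.min(dist)
      if (dist[j] <= 365) bmi_ref <- bmip$bmi[j]
    }
    med_ever <- c(insulin = FALSE, metformin = FALSE, sulfonylurea = FALSE)
    if (cohort$arm[i] == "diabetes") {
      me <- medication_exposure(dataset$medications[md_idx[[r]]], win)
      med_ever <- stats::setNames(me$ever, me$drug_class)[names(med_ever)]
    }
    cancer_date <- function(site) {
      d <- ca$diagnosis_date[ca$site == site]
      if (length(d)) d[1] else as.Date(NA)
    }
    out[[i]] <- data.frame(
      patient_id = pid,
      age_at_reference = age_completed_years(pats$birth_date[r], win$reference_date),
      gender = pats$gender[r],
      insured = pats$insured[r],
      bmi_at_reference = bmi_ref,
      observation_years_before = as.numeric(win$reference_date - win$lookback_start) / 365,
      observation_years_after = as.numeric(win$followup_end - win$reference_date) / 365,
      visits_pre_bin = vf$pre_bin, visits_post_bin = vf$post_bin,
      breast_cancer = !is.na(cancer_date("breast")),
      prostate_cancer = !is.na(cancer_date("prostate")),
      colon_cancer = !is.na(cancer_date("colon")),
      breast_cancer_date = cancer_date("breast"),
      prostate_cancer_date = cancer_date("prostate"),
      colon_cancer_date = cancer_date("colon"),
      myocardial_infarction = com$myocardial_infarction,
      coronary_heart_disease = com$coronary_heart_disease,
      peripheral_vascular = com$peripheral_vascular,
      cardiovascular_disease = com$cardiovascular_disease,
      chronic_pulmonary = com$chronic_pulmonary,
      rheumatic_heart = com$rheumatic_heart,
      renal_disease = com$renal_disease,
      charlson_modified = com$charlson_modified,
      insulin_ever = med_ever[["insulin"]],
      metformin_ever = med_ever[["metformin"]],
      sulfonylurea_ever = med_ever[["sulfonylurea"]]
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

AGE_GROUPS <- c("30-49", "50-59", "60-69", "70-79", ">=80")

#' Achieved control:case matching ratio
#'
#' Reported to one decimal, as matching ratios conventionally are (a
#' 5:1 design with post-match losses yields e.g. 4.8).
#'
#' @param n_cases,n_controls Final arm sizes.
#' @return Numeric scalar.
#' @export
achieved_matching_ratio <- function(n_cases, n_controls) {
  round(n_controls / max(1, n_cases), 1)
}

#' Arm-stratified descriptive summary table
#'
#' Counts and percentages per categorical level by arm (gender, age
#' group, smoking, reference period, MESA residency, insurance, visit
#' bins, comorbidities, cancer sites), means with IQRs for age, BMI and
#' observation years, and the achieved matching ratio rounded to one
#' decimal.
#'
#' @param cohort The `cohort` data.frame from [build_cohort()].
#' @param covariates Output of [compute_covariates()].
#' @param dataset The [emr_dataset()] (for demographics).
#' @return List of class `cohort_summary`: `table` (long data.frame:
#'   `variable`, `level`, `arm`, `n`, `pct`), `continuous` (data.frame:
#'   `variable`, `arm`, `mean`, `q1`, `q3`), `n_cases`, `n_controls`,
#'   `achieved_ratio`.
#' @export
descriptive_summary <- function(cohort, covariates, dataset) {
  stopifnot(nrow(cohort) > 0)
  m <- merge(cohort, covariates, by = "patient_id")
  m <- merge(m, dataset$patients[, .(patient_id, smoking_ever_p = smoking_ever)],
             by = "patient_id")
  m$age_group <- AGE_GROUPS[findInterval(m$age_at_reference, c(0, 50, 60, 70, 80))]
  arms <- c("diabetes", "no_diabetes")
  n_arm <- stats::setNames(vapply(arms, function(a) sum(m$arm == a), numeric(1)), arms)

  cat_rows <- function(variable, value, levels) {
    do.call(rbind, lapply(arms, function(a) {
      v <- value[m$arm == a]
      n <- vapply(levels, function(l) sum(v == l, na.rm = TRUE), numeric(1))
      data.frame(variable = variable, level = levels, arm = a, n = n,
                 pct = if (n_arm[[a]] > 0) round(100 * n / n_arm[[a]], 1) else 0)
    }))
  }
  tab <- rbind(
    cat_rows("gender", m$gender, c("male", "female")),
    cat_rows("age_group", m$age_group, AGE_GROUPS),
    cat_rows("smoking", ifelse(m$smoking_ever_p, "ever", "never"), c("ever", "never")),
    cat_rows("reference_period", m$reference_period, REFERENCE_PERIODS),
    cat_rows("mesa_residency", ifelse(m$mesa_ever, "yes", "no"), c("no", "yes")),
    cat_rows("insurance", ifelse(isTRUE_v(m$insured), "yes", "no"), c("yes")),
    cat_rows("visits_pre", m$visits_pre_bin, VISIT_BINS),
    cat_rows("visits_post", m$visits_post_bin, VISIT_BINS),
    do.call(rbind, lapply(c("myocardial_infarction", "coronary_heart_disease",
                            "peripheral_vascular", "cardiovascular_disease",
                            "chronic_pulmonary", "rheumatic_heart", "renal_disease",
                            "breast_cancer", "prostate_cancer", "colon_cancer"),
                          function(v) cat_rows(v, ifelse(m[[v]], "yes", "no"), "yes")))
  )
  cont_rows <- function(variable, value) {
    do.call(rbind, lapply(arms, function(a) {
      v <- value[m$arm == a]
      q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
      data.frame(variable = variable, arm = a,
                 mean = mean(v, na.rm = TRUE), q1 = q[1], q3 = q[2])
    }))
  }
  cont <- rbind(cont_rows("age_years", m$age_at_reference),
                cont_rows("bmi", m$bmi_at_reference),
                cont_rows("observation_years_before", m$observation_years_before),
                cont_rows("observation_years_after", m$observation_years_after))
  structure(list(
    table = tab, continuous = cont,
    n_cases = unname(n_arm[["diabetes"]]), n_controls = unname(n_arm[["no_diabetes"]]),
    achieved_ratio = achieved_matching_ratio(n_arm[["diabetes"]], n_arm[["no_diabetes"]])
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: %d diabetes, %d no-diabetes (ratio %.1f)\n\n",
              x$n_cases, x$n_controls, x$achieved_ratio))
  wide <- x$table
  for (v in unique(wide$variable)) {
    cat(v, "\n")
    sub <- wide[wide$variable == v, ]
    for (l in unique(sub$level)) {
      d <- sub[sub$level == l & sub$arm == "diabetes", ]
      nd <- sub[sub$level == l & sub$arm == "no_diabetes", ]
      cat(sprintf("  %-10s %8d (%5.1f)  %8d (%5.1f)\n", l, d$n, d$pct, nd$n, nd$pct))
    }
  }
  invisible(x)
}
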