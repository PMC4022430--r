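#' Observation window censored at large EMR gaps
#'
#' A gap is a run of `gap_years` (default 4) or more consecutive calendar
#' years with zero encounters. The look-back start is January 1 of the
#' year after the latest gap ending before the reference year (or the
#' first encounter date if there is none); the follow-up end is the
#' earlier of `followup_end` and December 31 of the year before the first
#' gap starting after the reference year. Calendar years are counted from
#' the first encounter year through the year of `followup_end`.
#'
#' @param encounters data.frame with a `date` column (one patient), or a
#'   `Date` vector.
#' @param reference_date Time zero of the window.
#' @param followup_end Administrative end of follow-up.
#' @param gap_years Minimum gap length in calendar years.
#' @return List of class `observation_window`: `lookback_start`,
#'   `reference_date`, `followup_end`.
#' @export
censored_window <- function(encounters, reference_date, followup_end,
                            gap_years = 4) {
  dates <- if (inherits(encounters, "Date")) encounters else as_emr_date(encounters$date)
  reference_date <- as_emr_date(reference_date)
  followup_end <- as_emr_date(followup_end)
  if (length(dates) == 0) stopf("no encounters: reference date not covered")
  y0 <- min(year_of(dates))
  y1 <- year_of(followup_end)
  ry <- year_of(reference_date)
  if (ry < y0 || ry > y1 || reference_date > followup_end) {
    stopf("reference date %s outside encounter coverage", reference_date)
  }
  years <- y0:y1
  occupied <- years %in% unique(year_of(dates))
  runs <- rle(occupied)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  gap <- !runs$values & runs$lengths >= gap_years
  gap_start_year <- years[run_start[gap]]
  gap_end_year <- years[run_end[gap]]
  inside <- gap_start_year <= ry & ry <= gap_end_year
  if (any(inside)) {
    stopf("reference date %s falls inside an encounter gap (%d-%d)",
          reference_date, gap_start_year[inside][1], gap_end_year[inside][1])
  }
  pre <- gap_end_year[gap_end_year < ry]
  lookback_start <- if (length(pre) > 0) jan1(max(pre) + 1L) else min(dates)
  post <- gap_start_year[gap_start_year > ry]
  fu <- if (length(post) > 0) min(followup_end, dec31(min(post) - 1L)) else followup_end
  if (lookback_start > reference_date) {
    stopf("reference date %s precedes the censored look-back start %s",
          reference_date, lookback_start)
  }
  structure(list(lookback_start = lookback_start,
                 reference_date = reference_date,
                 followup_end = fu),
            class = "observation_window")
}

#' @export
print.observation_window <- function(x, ...) {
  cat(sprintf("<observation_window> [%s .. %s], reference %s\n",
              x$lookback_start, x$followup_end, x$reference_date))
  invisible(x)
}

#' Healthcare-engagement filter
#'
#' `TRUE` iff the patient has at least one diagnosis event that is either
#' flagged as a well-visit or does not match the diabetes-related code
#' set, in at least one of the `years_prior` calendar years strictly
#' before the reference year (optionally including the reference year).
#'
#' @param diagnoses data.frame with `date`, `code`, and optionally
#'   `is_well_visit` for one patient.
#' @param reference_date Reference date.
#' @param diabetes_related_codes A [code_set()].
#' @param years_prior Number of calendar years examined (default 3).
#' @param include_reference_year Also count the reference year itself.
#' @return Logical scalar.
#' @export
check_engagement <- function(diagnoses, reference_date, diabetes_related_codes,
                             years_prior = 3, include_reference_year = FALSE) {
  if (nrow(diagnoses) == 0) return(FALSE)
  ry <- year_of(as_emr_date(reference_date))
  lo <- ry - years_prior
  hi <- if (include_reference_year) ry else ry - 1L
  yr <- year_of(as_emr_date(diagnoses$date))
  well <- if ("is_well_visit" %in% names(diagnoses)) {
    isTRUE_v(diagnoses$is_well_visit)
  } else rep(FALSE, nrow(diagnoses))
  qualifying <- well | !code_matches(diagnoses$code, diabetes_related_codes)
  any(qualifying & yr >= lo & yr <= hi)
}

isTRUE_v <- function(x) !is.na(x) & x

#' Birth-year quintile cut points from the case distribution
#'
#' @param birth_dates `Date` vector of case birth dates.
#' @return Integer vector of 4 interior birth-year cut points.
#' @export
birth_quintile_cuts <- function(birth_dates) {
  yrs <- year_of(as_emr_date(birth_dates))
  as.integer(stats::quantile(yrs, probs = c(0.2, 0.4, 0.6, 0.8), type = 1, names = FALSE))
}

REFERENCE_PERIODS <- c("1995-1999", "2000-2004", "2005-2009")

reference_period_of <- function(reference_date) {
  ry <- year_of(as_emr_date(reference_date))
  idx <- findInterval(ry, c(1995, 2000, 2005, 2010))
  if (any(idx < 1 | idx > 3)) {
    stopf("reference year %s outside 1995-2009",
          paste(ry[idx < 1 | idx > 3], collapse = ", "))
  }
  REFERENCE_PERIODS[idx]
}

#' Matching stratum of a patient at a reference date
#'
#' Strata are the cross of birth-year category (five bins from four
#' interior cut points), ever-smoker status, ever-MESA residency, and the
#' reference period (1995-1999, 2000-2004, 2005-2009).
#'
#' @param patient One-row data.frame/list with `birth_date`,
#'   `smoking_ever`, `mesa_resident_ever`.
#' @param reference_date Reference date (onset for cases).
#' @param birth_cuts Integer vector of 4 interior birth-year cut points.
#' @return List of class `stratum_key`: `birth_category` (1-5),
#'   `smoking_ever`, `mesa_ever`, `reference_period`, and `key`, a single
#'   string identifying the stratum.
#' @export
stratify <- function(patient, reference_date, birth_cuts) {
  if (length(birth_cuts) != 4) stopf("birth_cuts must have 4 interior cut points")
  bc <- findInterval(year_of(as_emr_date(patient$birth_date)), sort(birth_cuts)) + 1L
  period <- reference_period_of(reference_date)
  key <- sprintf("b%d|smoke%d|mesa%d|%s", bc,
                 as.integer(patient$smoking_ever),
                 as.integer(patient$mesa_resident_ever), period)
  structure(list(birth_category = bc,
                 smoking_ever = patient$smoking_ever,
                 mesa_ever = patient$mesa_resident_ever,
                 reference_period = period, key = key),
            class = "stratum_key")
}

demo_key <- function(birth_category, smoking_ever, mesa_ever) {
  sprintf("b%d|smoke%d|mesa%d", birth_category,
          as.integer(smoking_ever), as.integer(mesa_ever))
}

#' Stratified frequency matching of controls to cases
#'
#' For each full stratum (demographics x reference period) holding `c`
#' cases, samples `min(ratio * c, available)` controls uniformly without
#' replacement from the eligible controls in the same demographic
#' stratum (controls have no reference period until a date is assigned).
#' Strata are processed in sorted key order and a control is used at most
#' once; shortfalls are logged per stratum.
#'
#' @param cases data.frame with `patient_id`, `stratum_key`, `demo_key`.
#' @param eligible_controls data.frame with `patient_id`, `demo_key`.
#' @param ratio Target controls per case.
#' @param seed Global seed (substream `"match"`).
#' @return List: `selected` (data.frame `patient_id`, `stratum_key`),
#'   `shortfalls` (data.frame `stratum_key`, `wanted`, `taken`),
#'   `achieved_ratio`.
#' @export
frequency_match <- function(cases, eligible_controls, ratio, seed) {
  stopifnot(ratio >= 1)
  strata <- sort(unique(cases$stratum_key))
  available <- split(eligible_controls$patient_id, eligible_controls$demo_key)
  selected <- vector("list", length(strata))
  shortfall <- vector("list", length(strata))
  with_substream(seed, "match", {
    for (i in seq_along(strata)) {
      s <- strata[i]
      n_cases <- sum(cases$stratum_key == s)
      dk <- sub("\\|[0-9]{4}-[0-9]{4}$", "", s)
      pool <- available[[dk]] %||% character()
      wanted <- ratio * n_cases
      take <- min(wanted, length(pool))
      pick <- if (take > 0) sort(sample(seq_along(pool), take)) else integer()
      selected[[i]] <- data.frame(patient_id = pool[pick], stratum_key = rep(s, take))
      available[[dk]] <- if (length(pick)) pool[-pick] else pool
      if (take < wanted) {
        shortfall[[i]] <- data.frame(stratum_key = s, wanted = wanted, taken = take)
      }
    }
  })
  sel <- do.call(rbind, selected)
  if (is.null(sel)) sel <- data.frame(patient_id = character(), stratum_key = character())
  sf <- Filter(Negate(is.null), shortfall)
  sf <- if (length(sf)) do.call(rbind, sf) else
    data.frame(stratum_key = character(), wanted = numeric(), taken = numeric())
  list(selected = sel, shortfalls = sf,
       achieved_ratio = nrow(sel) / max(1L, nrow(cases)))
}

#' Assign reference dates to matched controls
#'
#' Each control receives the onset date of a case drawn uniformly with
#' replacement from the cases in its stratum, so the distribution of
#' possible observation times for controls matches that of the cases in
#' the same stratum.
#'
#' @param matched_controls data.frame with `patient_id`, `stratum_key`.
#' @param cases data.frame with `patient_id`, `stratum_key`, `onset_date`.
#' @param seed Global seed (substream `"refdate"`).
#' @return data.frame: `patient_id`, `stratum_key`, `reference_date`,
#'   `matched_from_case`.
#' @export
assign_reference_dates <- function(matched_controls, cases, seed) {
  if (nrow(matched_controls) == 0) {
    return(data.frame(patient_id = character(), stratum_key = character(),
                      reference_date = as.Date(character()),
                      matched_from_case = character()))
  }
  case_by_stratum <- split(seq_len(nrow(cases)), cases$stratum_key)
  missing <- setdiff(unique(matched_controls$stratum_key), names(case_by_stratum))
  if (length(missing) > 0) {
    stopf("stratum with controls but zero cases: %s", paste(missing, collapse = ", "))
  }
  ord <- order(matched_controls$stratum_key, matched_controls$patient_id)
  mc <- matched_controls[ord, , drop = FALSE]
  with_substream(seed, "refdate", {
    pick <- vapply(mc$stratum_key, function(s) {
      idx <- case_by_stratum[[s]]
      idx[sample.int(length(idx), 1L)]
    }, integer(1))
  })
  data.frame(patient_id = mc$patient_id, stratum_key = mc$stratum_key,
             reference_date = cases$onset_date[pick],
             matched_from_case = cases$patient_id[pick],
             row.names = NULL)
}

window_or_null <- function(encounters, reference_date, followup_end, gap_years) {
  tryCatch(censored_window(encounters, reference_date, followup_end, gap_years),
           error = function(e) NULL)
}

#' Build the matched diabetes / no-diabetes cohort
#'
#' The full pipeline downstream of the phenotype: cases pass the
#' engagement filter, gap censoring, and the minimum post-reference
#' observation requirement, then define the strata (birth-year quintiles
#' unless `config$birth_cuts` is supplied); eligible controls are
#' frequency matched at `config$ratio`, receive reference dates sampled
#' from their stratum's case onsets, and then face the same engagement,
#' censoring, and minimum-observation filters at the assigned date.
#' Controls dropped after date assignment are not replaced, so the
#' achieved ratio can fall below the target. Every stage's count is
#' recorded in the attrition log.
#'
#' @param dataset An [emr_dataset()].
#' @param decisions Output of [evaluate_population()].
#' @param config A [run_config()].
#' @param seed Global seed; defaults to `config$seed`.
#' @return List of class `cohort_build`: `cohort` (data.frame with
#'   `patient_id`, `arm`, stratum fields, `reference_date`,
#'   `lookback_start`, `followup_end`, `matched_from_case`), `attrition`
#'   (data.frame `stage`, `arm`, `n`), `birth_cuts`, `shortfalls`,
#'   `achieved_ratio`.
#' @export
build_cohort <- function(dataset, decisions, config = run_config(),
                         seed = config$seed) {
  stopifnot(inherits(dataset, "emr_dataset"), inherits(config, "run_config"))
  pc <- config$phenotype
  pats <- dataset$patients
  attrition <- list()
  log_stage <- function(stage, arm, n) {
    attrition[[length(attrition) + 1L]] <<- data.frame(stage = stage, arm = arm, n = n)
  }

  enc_idx <- split(seq_len(nrow(dataset$encounters)),
                   factor(dataset$encounters$patient_id, levels = pats$patient_id))
  dx_idx <- split(seq_len(nrow(dataset$diagnoses)),
                  factor(dataset$diagnoses$patient_id, levels = pats$patient_id))
  row_of <- stats::setNames(seq_len(nrow(pats)), pats$patient_id)

  filter_members <- function(ids, ref_dates, arm) {
    keep <- logical(length(ids))
    windows <- vector("list", length(ids))
    n_engaged <- 0L
    for (i in seq_along(ids)) {
      r <- row_of[[ids[i]]]
      dxp <- dataset$diagnoses[dx_idx[[r]]]
      if (!check_engagement(dxp, ref_dates[i], pc$code_sets$diabetes_related,
                            config$engagement_years,
                            config$engagement_include_reference_year)) next
      n_engaged <- n_engaged + 1L
      w <- window_or_null(dataset$encounters$date[enc_idx[[r]]], ref_dates[i],
                          config$followup_end, config$gap_years)
      if (is.null(w)) next
      if (as.numeric(w$followup_end - w$reference_date) < config$min_observation_days) next
      keep[i] <- TRUE
      windows[[i]] <- w
    }
    log_stage("engagement", arm, n_engaged)
    log_stage("window_and_min_observation", arm, sum(keep))
    list(keep = keep, windows = windows)
  }

  # ---- cases ----
  case_dec <- decisions[decisions$status == "case", , drop = FALSE]
  log_stage("phenotype_cases", "diabetes", nrow(case_dec))
  # the reference date (onset) must fall inside the accrual window: a
  # second abnormal lab can precede the first in-window code by enough
  # to land before the study start
  in_accrual <- case_dec$onset_date >= pc$study_start &
    case_dec$onset_date <= pc$study_end
  case_dec <- case_dec[in_accrual, , drop = FALSE]
  log_stage("reference_in_accrual_window", "diabetes", nrow(case_dec))
  cf <- filter_members(case_dec$patient_id, case_dec$onset_date, "diabetes")
  case_dec <- case_dec[cf$keep, , drop = FALSE]
  case_windows <- cf$windows[cf$keep]

  birth_cuts <- config$birth_cuts %||%
    (if (nrow(case_dec) > 0) birth_quintile_cuts(pats$birth_date[row_of[case_dec$patient_id]])
     else stopf("no cases survive filtering and no birth_cuts configured"))

  case_strat <- lapply(seq_len(nrow(case_dec)), function(i) {
    stratify(pats[row_of[[case_dec$patient_id[i]]]], case_dec$onset_date[i], birth_cuts)
  })
  case_tbl <- data.frame(
    patient_id = case_dec$patient_id,
    stratum_key = vapply(case_strat, `[[`, character(1), "key"),
    demo_key = vapply(case_strat, function(s)
      demo_key(s$birth_category, s$smoking_ever, s$mesa_ever), character(1)),
    onset_date = case_dec$onset_date
  )

  # ---- controls ----
  ctrl_dec <- decisions[decisions$status == "control", , drop = FALSE]
  log_stage("phenotype_controls", "no_diabetes", nrow(ctrl_dec))
  ctrl_rows <- row_of[ctrl_dec$patient_id]
  ctrl_tbl <- data.frame(
    patient_id = ctrl_dec$patient_id,
    demo_key = demo_key(findInterval(year_of(pats$birth_date[ctrl_rows]),
                                     sort(birth_cuts)) + 1L,
                        pats$smoking_ever[ctrl_rows],
                        pats$mesa_resident_ever[ctrl_rows])
  )

  fm <- frequency_match(case_tbl, ctrl_tbl, config$ratio, seed)
  log_stage("frequency_matched", "no_diabetes", nrow(fm$selected))
  assigned <- assign_reference_dates(fm$selected, case_tbl, seed)
  ctf <- filter_members(assigned$patient_id, assigned$reference_date, "no_diabetes")
  assigned_kept <- assigned[ctf$keep, , drop = FALSE]
  ctrl_windows <- ctf$windows[ctf$keep]
  log_stage("final", "no_diabetes", nrow(assigned_kept))
  log_stage("final", "diabetes", nrow(case_dec))

  unpack_key <- function(keys) {
    parts <- strsplit(keys, "|", fixed = TRUE)
    data.frame(
      birth_category = as.integer(sub("^b", "", vapply(parts, `[`, character(1), 1))),
      smoking_ever = vapply(parts, `[`, character(1), 2) == "smoke1",
      mesa_ever = vapply(parts, `[`, character(1), 3) == "mesa1",
      reference_period = vapply(parts, `[`, character(1), 4)
    )
  }
  win_col <- function(ws, field) as.Date(vapply(ws, function(w)
    as.character(w[[field]]), character(1)))

  mk_rows <- function(ids, arm, keys, refs, windows, matched_from) {
    if (length(ids) == 0) {
      return(cbind(data.frame(patient_id = character(), arm = character()),
                   unpack_key(character()),
                   data.frame(reference_date = as.Date(character()),
                              lookback_start = as.Date(character()),
                              followup_end = as.Date(character()),
                              matched_from_case = character())))
    }
    cbind(data.frame(patient_id = ids, arm = arm),
          unpack_key(keys),
          data.frame(reference_date = refs,
                     lookback_start = win_col(windows, "lookback_start"),
                     followup_end = win_col(windows, "followup_end"),
                     matched_from_case = matched_from))
  }
  cohort <- rbind(
    mk_rows(case_tbl$patient_id, "diabetes", case_tbl$stratum_key,
            case_tbl$onset_date, case_windows, NA_character_),
    mk_rows(assigned_kept$patient_id, "no_diabetes", assigned_kept$stratum_key,
            assigned_kept$reference_date, ctrl_windows,
            assigned_kept$matched_from_case)
  )
  rownames(cohort) <- NULL
  structure(list(
    cohort = cohort,
    attrition = do.call(rbind, attrition),
    birth_cuts = birth_cuts,
    shortfalls = fm$shortfalls,
    achieved_ratio = nrow(assigned_kept) / max(1L, nrow(case_dec))
  ), class = "cohort_build")
}

#' @export
print.cohort_build <- function(x, ...) {
  n_case <- sum(x$cohort$arm == "diabetes")
  n_ctrl <- sum(x$cohort$arm == "no_diabetes")
  cat(sprintf("<cohort_build> %d diabetes, %d no-diabetes (achieved ratio %.1f)\n",
              n_case, n_ctrl, x$achieved_ratio))
  invisible(x)
}
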