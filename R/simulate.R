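#' Parameters of the synthetic EMR simulator
#'
#' The simulator emulates the data-generating world the phenotype
#' assumes: type 2 diabetes develops gradually, with a latent HbA1c
#' trajectory drifting upward before clinical onset (defined as the day
#' the trajectory crosses the diagnostic threshold, 6.5 percent) and
#' faster afterwards; testing is driven by a healthcare-visit process
#' (diabetics visit more often); an abnormal result usually triggers a
#' confirmatory retest a few weeks later, as clinical practice requires;
#' the first diagnostic code trails biochemical onset by an exponential
#' coding lag and lands on a visit date; medications start after coding.
#' Glucose analytes are a linear stochastic transform of latent HbA1c
#' whose default coefficients are calibrated so the fasting threshold
#' (126 mg/dL) and the HbA1c threshold (6.5 percent) are crossed at the
#' same latent time, mirroring the intent of the ADA criteria; the
#' average-glucose (eAG) intercept of -46.7 can be configured instead.
#'
#' @param n_patients Total simulated patients.
#' @param fraction_true_t2d Fraction with true type 2 diabetes.
#' @param fraction_type1_distractors Fraction with type 1 diabetes
#'   (carry 250.X1/250.X3 codes and insulin).
#' @param visit_rate_t2d,visit_rate_other Visits per year by arm
#'   (diabetic vs non-diabetic).
#' @param lab_test_prob_per_visit Probability a visit includes a
#'   glycemic lab.
#' @param baseline_hba1c_mean,baseline_hba1c_sd Latent baseline HbA1c
#'   (percent).
#' @param preonset_drift_per_year,postonset_drift_per_year Latent HbA1c
#'   slope (percent/year) before and after onset.
#' @param coding_lag_mean_days Mean of the exponential delay from true
#'   onset to the first type 2 code.
#' @param med_start_lag_days Days from first code to first antidiabetic
#'   medication.
#' @param miscode_prob Probability a diabetes code's fifth digit is
#'   flipped (type 2 <-> type 1).
#' @param measurement_noise_sd HbA1c assay noise (percent, s.d.).
#' @param retest_prob Probability an abnormal lab triggers a
#'   confirmatory retest 14-42 days later (the ADA criteria require a
#'   repeat test to confirm an abnormal result, ordinarily without
#'   delay).
#' @param surveillance_lab_prob Per-visit lab probability once a patient
#'   has had any abnormal result: an unexplained abnormal puts the
#'   patient under glycemic monitoring, so later visits are tested more
#'   often than the routine screening rate.
#' @param glucose_slope,fasting_intercept,fasting_noise_sd Fasting
#'   glucose = slope * HbA1c + intercept + noise.
#' @param random_offset,random_noise_sd Random glucose = fasting latent
#'   + offset + noise.
#' @param engagement_dx_prob Probability a visit carries a benign
#'   (non-diabetes) diagnosis code.
#' @param well_visit_prob Probability a visit carries a well-visit code.
#' @param comorbidity_prob,cancer_prob Per-patient probabilities of a
#'   comorbid condition / a cancer (two or more codes each).
#' @param study_start,study_end,followup_end,entry_start Calendar frame;
#'   patients enter the EMR uniformly between `entry_start` and
#'   `study_start`, true onsets fall uniformly in the study window.
#' @param onset_definition `"hba1c_crossing"` (default) or
#'   `"fasting_crossing"`: which latent threshold crossing defines the
#'   recorded true onset date.
#' @param seed Default seed used when [simulate_population()] is not
#'   given one.
#' @return List of class `simulation_params`.
#' @export
simulation_params <- function(n_patients = 10000,
                              fraction_true_t2d = 0.2,
                              fraction_type1_distractors = 0.02,
                              visit_rate_t2d = 4,
                              visit_rate_other = 2.5,
                              lab_test_prob_per_visit = 0.5,
                              baseline_hba1c_mean = 5.3,
                              baseline_hba1c_sd = 0.35,
                              preonset_drift_per_year = 0.3,
                              postonset_drift_per_year = 1.0,
                              coding_lag_mean_days = 180,
                              med_start_lag_days = 60,
                              miscode_prob = 0.005,
                              measurement_noise_sd = 0.15,
                              retest_prob = 0.8,
                              glucose_slope = 28.7,
                              fasting_intercept = 126 - 28.7 * 6.5,
                              fasting_noise_sd = 6,
                              random_offset = 45,
                              surveillance_lab_prob = 0.9,
                              random_noise_sd = 30,
                              engagement_dx_prob = 0.35,
                              well_visit_prob = 0.04,
                              comorbidity_prob = 0.12,
                              cancer_prob = 0.04,
                              study_start = as.Date("1995-01-01"),
                              study_end = as.Date("2009-12-31"),
                              followup_end = as.Date("2011-12-31"),
                              entry_start = as.Date("1985-01-01"),
                              onset_definition = c("hba1c_crossing", "fasting_crossing"),
                              seed = 1L) {
  probs <- c(fraction_true_t2d, fraction_type1_distractors,
             lab_test_prob_per_visit, miscode_prob, retest_prob,
             surveillance_lab_prob, engagement_dx_prob, well_visit_prob,
             comorbidity_prob, cancer_prob)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (fraction_true_t2d + fraction_type1_distractors > 1) {
    stopf("status fractions must sum to at most 1")
  }
  pos <- c(n_patients, visit_rate_t2d, visit_rate_other, baseline_hba1c_sd,
           preonset_drift_per_year, postonset_drift_per_year,
           coding_lag_mean_days, measurement_noise_sd, fasting_noise_sd,
           random_noise_sd)
  if (any(!is.finite(pos)) || any(pos <= 0)) stopf("rates and s.d.s must be positive")
  p <- as.list(environment())
  p$onset_definition <- match.arg(onset_definition)
  p$study_start <- as_emr_date(study_start)
  p$study_end <- as_emr_date(study_end)
  p$followup_end <- as_emr_date(followup_end)
  p$entry_start <- as_emr_date(entry_start)
  structure(p, class = "simulation_params")
}

# Concrete codes used when the simulator emits events for each category.
SIM_CODE_POOLS <- list(
  benign = c("401.9", "272.4", "724.2", "465.9", "719.46", "780.79"),
  well = "V70.0",
  type2 = c("250.00", "250.02"),
  type1 = c("250.01", "250.03"),
  myocardial_infarction = c("410.01", "410.11", "412"),
  coronary_heart_disease = c("414.01", "414.8", "411.1"),
  peripheral_vascular = c("443.9", "440.21"),
  cardiovascular_disease = c("434.91", "435.9", "436"),
  chronic_pulmonary = c("491.21", "493.90", "496"),
  rheumatic_heart = c("394.0", "397.0"),
  renal_disease = c("585", "586"),
  breast = c("174.9", "174.4"),
  prostate = "185",
  colon = c("153.9", "153.3")
)

flip_fifth_digit <- function(code) {
  map <- c("250.00" = "250.01", "250.01" = "250.00",
           "250.02" = "250.03", "250.03" = "250.02")
  unname(map[code])
}

latent_hba1c <- function(status, baseline, onset, date, p) {
  dy <- as.numeric(date - onset) / 365
  traj <- 6.5 + ifelse(dy < 0, p$preonset_drift_per_year, p$postonset_drift_per_year) * dy
  ifelse(status == "none", baseline, pmin(pmax(baseline, traj), 13))
}

#' Simulate a longitudinal EMR population with known ground truth
#'
#' See [simulation_params()] for the generative model. All randomness
#' flows from `seed` through named substreams (demographics, visits,
#' labs, retests, coding, comorbidities, medications, bmi), so stages
#' are independently reproducible and the whole dataset is byte-identical
#' under a fixed seed.
#'
#' @param params A [simulation_params()].
#' @param seed Integer seed (defaults to `params$seed`).
#' @return List: `dataset` (an [emr_dataset()]) and `truth` (data.frame
#'   `patient_id`, `true_status`, `true_onset_date` — onset present iff
#'   the status is `t2d`).
#' @export
simulate_population <- function(params = simulation_params(), seed = params$seed) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  n <- p$n_patients
  n_t2 <- round(n * p$fraction_true_t2d)
  n_t1 <- round(n * p$fraction_type1_distractors)
  status <- c(rep("t2d", n_t2), rep("t1d", n_t1), rep("none", n - n_t2 - n_t1))
  pid <- sprintf("P%06d", seq_len(n))

  birth_span <- as.numeric(as.Date("1975-12-31") - as.Date("1920-01-01"))
  entry_span <- as.numeric(p$study_start - p$entry_start)
  onset_span <- as.numeric(p$study_end - p$study_start)
  demo <- with_substream(seed, "demographics", {
    list(birth = as.Date("1920-01-01") + floor(stats::runif(n) * birth_span),
         gender = sample(c("male", "female"), n, replace = TRUE),
         smoking = stats::runif(n) < 0.67,
         mesa = stats::runif(n) < 0.196,
         insured = stats::runif(n) < 0.77,
         entry = p$entry_start + floor(stats::runif(n) * entry_span),
         baseline = pmin(pmax(stats::rnorm(n, p$baseline_hba1c_mean,
                                           p$baseline_hba1c_sd), 4.5), 6.3),
         onset = p$study_start + floor(stats::runif(n) * (onset_span + 1)))
  })
  onset <- demo$onset
  onset[status == "none"] <- NA

  # visit process: homogeneous Poisson at the arm's rate from entry to
  # the end of follow-up
  rate <- ifelse(status == "none", p$visit_rate_other, p$visit_rate_t2d)
  span_days <- as.numeric(p$followup_end - demo$entry)
  visits <- with_substream(seed, "visits", {
    n_vis <- stats::rpois(n, rate * span_days / 365)
    i <- rep(seq_len(n), n_vis)
    data.table::data.table(
      idx = i,
      date = demo$entry[i] + floor(stats::runif(length(i)) * span_days[i]))
  })
  visits <- unique(visits, by = c("idx", "date"))
  data.table::setorder(visits, idx, date)

  observe_lab <- function(idx, date, analyte, noise_h, noise_g) {
    lat <- latent_hba1c(status[idx], demo$baseline[idx], onset[idx], date, p)
    fast_lat <- p$glucose_slope * lat + p$fasting_intercept
    value <- numeric(length(idx))
    h <- analyte == "hba1c"
    f <- analyte == "fasting_glucose"
    r <- analyte == "random_glucose"
    value[h] <- round(lat[h] + noise_h[h], 1)
    value[f] <- round(fast_lat[f] + noise_g[f])
    value[r] <- round(fast_lat[r] + p$random_offset + noise_g[r] * p$random_noise_sd / p$fasting_noise_sd)
    pmax(value, ifelse(h, 3.5, 40))
  }
  lab_abnormal_sim <- function(analyte, value) {
    thr <- c(hba1c = 6.5, fasting_glucose = 126, random_glucose = 200)
    value >= thr[analyte]
  }

  labs <- with_substream(seed, "labs", {
    take <- stats::runif(nrow(visits)) < p$lab_test_prob_per_visit
    lv <- visits[take]
    lv[, analyte := sample(c("hba1c", "fasting_glucose", "random_glucose"),
                           .N, replace = TRUE, prob = c(0.5, 0.3, 0.2))]
    lv[, value := observe_lab(idx, date, analyte,
                              stats::rnorm(.N, 0, p$measurement_noise_sd),
                              stats::rnorm(.N, 0, p$fasting_noise_sd))]
    # surveillance: from the first abnormal screening result on, the
    # remaining (untested) visits carry a lab often enough to lift the
    # per-visit probability to surveillance_lab_prob
    abn <- lv[lab_abnormal_sim(analyte, value)]
    first_abn <- abn[, .(first_abn = min(date)), by = idx]
    extra_p <- max(0, (p$surveillance_lab_prob - p$lab_test_prob_per_visit) /
                     (1 - p$lab_test_prob_per_visit))
    mon <- visits[!take][first_abn, on = "idx", nomatch = NULL][date > first_abn]
    mon <- mon[stats::runif(nrow(mon)) < extra_p]
    if (nrow(mon) > 0) {
      mon[, analyte := sample(c("hba1c", "fasting_glucose", "random_glucose"),
                              .N, replace = TRUE, prob = c(0.6, 0.3, 0.1))]
      mon[, value := observe_lab(idx, date, analyte,
                                 stats::rnorm(.N, 0, p$measurement_noise_sd),
                                 stats::rnorm(.N, 0, p$fasting_noise_sd))]
      lv <- rbind(lv, mon[, names(lv), with = FALSE])
    }
    lv
  })

  # confirmatory retesting: an abnormal result is usually repeated a few
  # weeks later (one round)
  retests <- with_substream(seed, "retests", {
    abn <- labs[lab_abnormal_sim(analyte, value)]
    keep <- stats::runif(nrow(abn)) < p$retest_prob
    rt <- abn[keep]
    rt[, date := date + sample(14:42, .N, replace = TRUE)]
    rt <- rt[date <= p$followup_end]
    rt[, value := observe_lab(idx, date, analyte,
                              stats::rnorm(.N, 0, p$measurement_noise_sd),
                              stats::rnorm(.N, 0, p$fasting_noise_sd))]
    rt
  })
  all_labs <- rbind(labs, retests)

  encounters <- rbind(visits[, .(idx, date, kind = "office")],
                      retests[, .(idx, date, kind = "lab_followup")])
  encounters <- unique(encounters, by = c("idx", "date", "kind"))
  data.table::setorder(encounters, idx, date)

  # diagnosis coding: first diabetes code at the first encounter on or
  # after onset + exponential lag; later encounters repeat the code
  diabetic <- which(status != "none")
  coding <- with_substream(seed, "coding", {
    lag <- stats::rexp(length(diabetic), 1 / p$coding_lag_mean_days)
    target <- data.table::data.table(idx = diabetic,
                                     date = demo$onset[diabetic] + round(lag))
    enc <- unique(encounters[, .(idx, date, snap = date)], by = c("idx", "date"))
    data.table::setkey(enc, idx, date)
    snapped <- enc[target, roll = -Inf]
    first_code <- snapped$snap
    later <- encounters[first_code[match(idx, diabetic)] < date &
                          !is.na(first_code[match(idx, diabetic)])]
    later <- later[stats::runif(nrow(later)) < 0.3]
    first_dt <- data.table::data.table(idx = diabetic, date = first_code)[!is.na(date)]
    codes <- rbind(first_dt, later[, .(idx, date)])
    pool2 <- SIM_CODE_POOLS$type2
    pool1 <- SIM_CODE_POOLS$type1
    codes[, code := ifelse(status[idx] == "t2d",
                           sample(pool2, .N, replace = TRUE),
                           sample(pool1, .N, replace = TRUE))]
    flip <- stats::runif(nrow(codes)) < p$miscode_prob
    codes[flip, code := flip_fifth_digit(code)]
    list(codes = codes, first_code = first_code)
  })
  first_code <- rep(as.Date(NA), n)
  first_code[diabetic] <- coding$first_code

  engagement <- with_substream(seed, "engagement", {
    take <- stats::runif(nrow(visits)) < p$engagement_dx_prob
    ben <- visits[take]
    ben[, code := sample(SIM_CODE_POOLS$benign, .N, replace = TRUE)]
    ben[, is_well := FALSE]
    wv <- visits[stats::runif(nrow(visits)) < p$well_visit_prob]
    wv[, code := SIM_CODE_POOLS$well]
    wv[, is_well := TRUE]
    rbind(ben[, .(idx, date, code, is_well)], wv[, .(idx, date, code, is_well)])
  })

  visit_dates <- split(visits$date, factor(visits$idx, levels = seq_len(n)))
  extra_dx <- with_substream(seed, "comorbidities", {
    conds <- c("myocardial_infarction", "coronary_heart_disease",
               "peripheral_vascular", "cardiovascular_disease",
               "chronic_pulmonary", "rheumatic_heart", "renal_disease")
    rows <- list()
    has_com <- which(stats::runif(n) < p$comorbidity_prob)
    for (i in has_com) {
      vd <- visit_dates[[i]]
      if (length(vd) < 2) next
      cond <- sample(conds, 1)
      k <- min(sample(2:4, 1), length(vd))
      rows[[length(rows) + 1L]] <- data.table::data.table(
        idx = i, date = sample(vd, k),
        code = sample(SIM_CODE_POOLS[[cond]], k, replace = TRUE), is_well = FALSE)
    }
    has_ca <- which(stats::runif(n) < p$cancer_prob)
    for (i in has_ca) {
      vd <- visit_dates[[i]]
      if (length(vd) < 2) next
      site <- if (demo$gender[i] == "female") {
        sample(c("breast", "colon"), 1, prob = c(0.6, 0.4))
      } else {
        sample(c("prostate", "colon"), 1, prob = c(0.6, 0.4))
      }
      k <- min(sample(2:3, 1), length(vd))
      rows[[length(rows) + 1L]] <- data.table::data.table(
        idx = i, date = sample(vd, k),
        code = sample(SIM_CODE_POOLS[[site]], k, replace = TRUE), is_well = FALSE)
    }
    if (length(rows)) data.table::rbindlist(rows) else
      data.table::data.table(idx = integer(), date = as.Date(character()),
                             code = character(), is_well = logical())
  })

  diagnoses <- rbind(
    coding$codes[, .(idx, date, code, is_well = FALSE)],
    engagement, extra_dx)

  meds <- with_substream(seed, "medications", {
    rows <- list()
    t2_coded <- diabetic[status[diabetic] == "t2d" & !is.na(first_code[diabetic])]
    if (length(t2_coded) > 0) {
      met <- data.table::data.table(idx = t2_coded, drug_class = "metformin",
                                    start_date = first_code[t2_coded] + p$med_start_lag_days)
      sulf_take <- stats::runif(length(t2_coded)) < 0.4
      sulf <- data.table::data.table(idx = t2_coded[sulf_take], drug_class = "sulfonylurea",
                                     start_date = first_code[t2_coded[sulf_take]] +
                                       p$med_start_lag_days + 365)
      ins_take <- stats::runif(length(t2_coded)) < 0.25
      ins <- data.table::data.table(idx = t2_coded[ins_take], drug_class = "insulin",
                                    start_date = first_code[t2_coded[ins_take]] +
                                      p$med_start_lag_days + 730)
      rows <- list(met, sulf, ins)
    }
    t1_coded <- diabetic[status[diabetic] == "t1d" & !is.na(first_code[diabetic])]
    if (length(t1_coded) > 0) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        idx = t1_coded, drug_class = "insulin",
        start_date = first_code[t1_coded] + p$med_start_lag_days)
    }
    md <- if (length(rows)) data.table::rbindlist(rows) else
      data.table::data.table(idx = integer(), drug_class = character(),
                             start_date = as.Date(character()))
    md[start_date <= p$followup_end]
  })

  bmi <- with_substream(seed, "bmi", {
    person_bmi <- pmax(stats::rnorm(n, ifelse(status == "none", 29, 33), 5), 17)
    take <- stats::runif(nrow(visits)) < 0.25
    bv <- visits[take]
    bv[, bmi := round(pmax(person_bmi[idx] + stats::rnorm(.N, 0, 1.5), 15), 1)]
    bv
  })

  true_onset <- onset
  if (p$onset_definition == "fasting_crossing") {
    latent_at_fasting_thr <- (126 - p$fasting_intercept) / p$glucose_slope
    shift_days <- round((6.5 - latent_at_fasting_thr) /
                          p$preonset_drift_per_year * 365)
    true_onset <- onset - shift_days
  }

  patients <- data.frame(patient_id = pid, birth_date = demo$birth,
                         gender = demo$gender, smoking_ever = demo$smoking,
                         mesa_resident_ever = demo$mesa, insured = demo$insured)
  ds <- emr_dataset(
    patients,
    diagnoses = diagnoses[, .(patient_id = pid[idx], date, code, is_well_visit = is_well)],
    labs = all_labs[, .(patient_id = pid[idx], date, analyte, value)],
    medications = meds[, .(patient_id = pid[idx], drug_class, start_date,
                           stop_date = as.Date(NA))],
    encounters = encounters[, .(patient_id = pid[idx], date, kind)],
    bmi = bmi[, .(patient_id = pid[idx], date, bmi)],
    study_window = c(p$study_start, p$study_end),
    followup_end = p$followup_end
  )
  truth <- data.frame(patient_id = pid, true_status = status,
                      true_onset_date = as.Date(ifelse(status == "t2d", true_onset, NA),
                                                origin = "1970-01-01"))
  list(dataset = ds, truth = truth)
}

#' Onset-date error distribution against ground truth
#'
#' For every algorithm-detected case whose true status is type 2
#' diabetes, the signed error is the assigned onset date minus the true
#' onset date in days; the summary reports the proportion of such
#' patients whose absolute error is at most `within_days` (183 d, i.e.
#' six months, by default) together with error quantiles.
#'
#' @param decisions Output of [evaluate_population()].
#' @param truth Ground-truth table from [simulate_population()].
#' @param within_days Agreement tolerance in days.
#' @return List of class `onset_error_summary`: `errors` (data.frame
#'   `patient_id`, `error_days`), `n_evaluable`, `prop_within`,
#'   `within_days`, `quantiles`.
#' @export
onset_error_distribution <- function(decisions, truth, within_days = 183) {
  det <- decisions[decisions$status == "case", c("patient_id", "onset_date")]
  tru <- truth[truth$true_status == "t2d" & !is.na(truth$true_onset_date),
               c("patient_id", "true_onset_date")]
  m <- merge(det, tru, by = "patient_id")
  if (nrow(m) == 0) stopf("no evaluable patients: detected cases and true cases are disjoint")
  err <- as.numeric(m$onset_date - m$true_onset_date)
  structure(list(
    errors = data.frame(patient_id = m$patient_id, error_days = err),
    n_evaluable = nrow(m),
    prop_within = mean(abs(err) <= within_days),
    within_days = within_days,
    quantiles = stats::quantile(err, c(0.05, 0.25, 0.5, 0.75, 0.95))
  ), class = "onset_error_summary")
}

#' @export
print.onset_error_summary <- function(x, ...) {
  cat(sprintf("Onset-date agreement: %d evaluable cases; %.1f%% within %d days\n",
              x$n_evaluable, 100 * x$prop_within, x$within_days))
  cat("Signed error quantiles (days):\n")
  print(round(x$quantiles))
  invisible(x)
}
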