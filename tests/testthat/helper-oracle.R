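# Independent oracles. These deliberately avoid the package's own code
# paths: code matching is done by exhaustive enumeration of wildcard
# expansions, the phenotype by direct set operations over plain vectors,
# gap censoring by scanning a year-occupancy vector, and the exact
# binomial bound by bisection on the binomial tail.

expand_icd9_pattern <- function(pattern) {
  p <- gsub(".", "", pattern, fixed = TRUE)
  chars <- strsplit(p, "")[[1]]
  slots <- lapply(chars, function(ch) if (ch == "X") as.character(0:9) else ch)
  apply(expand.grid(slots, stringsAsFactors = FALSE), 1, paste, collapse = "")
}

oracle_code_match <- function(codes, patterns) {
  expanded <- unlist(lapply(patterns, expand_icd9_pattern))
  gsub(".", "", codes, fixed = TRUE) %in% expanded
}

oracle_age <- function(birth, at) {
  # count whole birthdays passed
  a <- 0L
  repeat {
    nxt <- seq(birth, by = "1 year", length.out = a + 2)[a + 2]
    if (nxt > at) break
    a <- a + 1L
  }
  a
}

# Independent re-derivation of the case/control decision from the stated
# criteria. dx: data.frame(date, code); labs: data.frame(date, analyte,
# value); meds: data.frame(drug_class, start_date).
oracle_decision <- function(birth_date, dx, labs, meds, cfg) {
  pat <- function(nm) cfg$code_sets[[nm]]$patterns
  thr <- c(hba1c = cfg$hba1c_threshold, fasting_glucose = cfg$fasting_threshold,
           random_glucose = cfg$random_threshold)
  abn <- labs$value >= thr[labs$analyte]
  anti <- meds$drug_class %in% c("insulin", "metformin", "sulfonylurea",
                                 "other_antidiabetic")
  rel <- oracle_code_match(dx$code, pat("diabetes_related"))
  t2 <- oracle_code_match(dx$code, pat("type2"))
  t1 <- oracle_code_match(dx$code, pat("type1"))

  reasons <- character()
  if (oracle_age(birth_date, cfg$study_end) < cfg$min_age_years) {
    reasons <- c(reasons, "age_below_minimum")
  }
  if (any(dx$date[rel] < cfg$study_start)) {
    reasons <- c(reasons, "prestudy_diabetes_related_code")
  }
  if (any(meds$start_date[anti] < cfg$study_start)) {
    reasons <- c(reasons, "prestudy_diabetes_medication")
  }
  if (length(reasons) > 0) {
    return(list(status = "ineligible", onset = as.Date(NA), reasons = reasons))
  }

  t2_in <- t2 & dx$date >= cfg$study_start & dx$date <= cfg$study_end
  if (sum(t2_in) == 0) {
    if (nrow(dx) + nrow(labs) + nrow(meds) == 0) {
      return(list(status = "ineligible", onset = as.Date(NA),
                  reasons = "no_normal_lab"))
    }
    if (any(dx$date[rel] <= cfg$study_end)) {
      reasons <- c(reasons, "diabetes_related_code")
    }
    normal <- labs$date[!abn & labs$date <= cfg$study_end]
    if (length(normal) == 0) reasons <- c(reasons, "no_normal_lab")
    if (any(meds$start_date[anti] <= cfg$study_end)) {
      reasons <- c(reasons, "diabetes_medication")
    }
    if (isTRUE(cfg$exclude_probable_undiagnosed) &&
        length(unique(labs$date[abn & labs$date <= cfg$study_end])) >= 2) {
      reasons <- c(reasons, "probable_undiagnosed_diabetes")
    }
    st <- if (length(reasons) == 0) "control" else "excluded"
    return(list(status = st, onset = as.Date(NA), reasons = reasons))
  }

  fc <- min(dx$date[t2_in])
  if (any(dx$date[t1] <= fc + cfg$type1_precedence)) {
    reasons <- c(reasons, "type1_within_precedence")
  }
  abn_dates <- sort(unique(labs$date[abn]))
  if (any(abn_dates < fc - cfg$onset_window)) {
    reasons <- c(reasons, "abnormal_lab_gt_3y_before_code")
  }
  second <- if (length(abn_dates) >= 2) abn_dates[2] else as.Date(NA)
  if (is.na(second) || second < fc - cfg$onset_window) {
    reasons <- c(reasons, "insufficient_abnormal_labs")
  }
  normal_in <- labs$date[!abn] >= fc - cfg$onset_window & labs$date[!abn] < fc
  if (!any(normal_in)) reasons <- c(reasons, "no_normal_lab_within_3y")
  anchor <- if (cfg$med_anchor == "onset" && !is.na(second)) min(fc, second) else fc
  if (any(meds$start_date[anti] < anchor - cfg$med_exclusion_lead)) {
    reasons <- c(reasons, "med_before_onset")
  }
  if (length(reasons) == 0) {
    list(status = "case", onset = min(fc, second), reasons = character())
  } else {
    list(status = "excluded", onset = as.Date(NA), reasons = reasons)
  }
}

# Gap-censoring oracle: scan the year-occupancy vector directly.
oracle_window <- function(enc_dates, ref, fu_end, gap_years = 4) {
  yrs <- as.integer(format(enc_dates, "%Y"))
  y0 <- min(yrs); y1 <- as.integer(format(fu_end, "%Y"))
  occ <- (y0:y1) %in% yrs
  ry <- as.integer(format(ref, "%Y"))
  # enumerate empty runs
  gaps <- list()
  i <- 1
  while (i <= length(occ)) {
    if (!occ[i]) {
      j <- i
      while (j < length(occ) && !occ[j + 1]) j <- j + 1
      if (j - i + 1 >= gap_years) gaps[[length(gaps) + 1]] <- c(y0 + i - 1, y0 + j - 1)
      i <- j + 1
    } else i <- i + 1
  }
  lb <- min(enc_dates)
  fu <- fu_end
  for (g in gaps) {
    if (g[1] <= ry && ry <= g[2]) return(NULL)  # reference uncovered
    if (g[2] < ry) lb <- as.Date(sprintf("%d-01-01", g[2] + 1))
    if (g[1] > ry && fu == fu_end) fu <- min(fu, as.Date(sprintf("%d-12-31", g[1] - 1)))
  }
  list(lookback_start = lb, followup_end = fu)
}

# Clopper-Pearson lower bound by bisection on the binomial upper tail.
oracle_cp_lower <- function(s, n, alpha = 0.05) {
  if (s == 0) return(0)
  f <- function(p) stats::pbinom(s - 1, n, p, lower.tail = FALSE) - alpha / 2
  lo <- 1e-12; hi <- 1 - 1e-12
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Random small patient for property tests: up to max_events events drawn
# from code/lab/medication pools that straddle every decision boundary.
random_patient <- function(max_events = 10) {
  n_ev <- sample(0:max_events, 1)
  kind <- if (n_ev > 0) sample(c("dx", "lab", "med"), n_ev, replace = TRUE,
                               prob = c(0.45, 0.45, 0.1)) else character()
  rand_date <- function(n) as.Date("1990-01-01") + sample.int(8035, n, replace = TRUE)
  code_pool <- c("250.00", "250.02", "250.01", "250.03", "250.11", "362.01",
                 "357.2", "583.81", "401.9", "V70.0", "174.9")
  n_dx <- sum(kind == "dx"); n_lab <- sum(kind == "lab"); n_med <- sum(kind == "med")
  dx <- data.frame(date = rand_date(n_dx),
                   code = sample(code_pool, n_dx, replace = TRUE))
  analyte <- sample(c("hba1c", "fasting_glucose", "random_glucose"),
                    n_lab, replace = TRUE)
  val_for <- function(a) switch(a,
    hba1c = sample(c(5.4, 6.2, 6.5, 7.3), 1),
    fasting_glucose = sample(c(95, 125, 126, 160), 1),
    random_glucose = sample(c(140, 199, 200, 260), 1))
  labs <- data.frame(date = rand_date(n_lab), analyte = analyte,
                     value = if (n_lab > 0) vapply(analyte, val_for, numeric(1)) else numeric())
  meds <- data.frame(drug_class = sample(c("metformin", "insulin", "sulfonylurea",
                                           "non_diabetes"), n_med, replace = TRUE),
                     start_date = rand_date(n_med))
  list(
    patient = list(patient_id = "RP", birth_date = as.Date("1900-01-01") +
                     sample.int(31000, 1)),
    dx = dx, labs = labs, meds = meds
  )
}

# Compare a package case_decision with an oracle decision.
expect_decision_matches <- function(dec, ora, info = NULL) {
  expect_identical(dec$status, ora$status, info = info)
  expect_true(setequal(dec$reasons, ora$reasons), info = info)
  if (ora$status == "case") {
    expect_identical(as.character(dec$onset_date), as.character(ora$onset), info = info)
  }
}
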