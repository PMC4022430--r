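pt <- list(patient_id = "P1", birth_date = as.Date("1950-06-15"))

test_that("lab classification applies ADA thresholds with >= as abnormal", {
  cfg <- default_cfg
  res <- classify_lab(c("hba1c", "hba1c", "random_glucose", "fasting_glucose",
                        "fasting_glucose"),
                      c(6.5, 6.49, 200, 125.9, 126), cfg)
  expect_identical(res$label, c("abnormal", "normal", "abnormal", "normal",
                                "abnormal"))
  expect_identical(res$threshold_used, c(6.5, 6.5, 200, 126, 126))
  expect_error(classify_lab("urine_glitter", 1, cfg), "unknown analyte")
})

test_that("first type 2 code date respects code set and study window", {
  cfg <- default_cfg
  expect_identical(
    first_type2_code_date(mk_dx(c("2001-04-02", "2003-01-01"),
                                c("250.00", "250.02")), cfg),
    as.Date("2001-04-02"))
  # 250.01 is a type 1 fifth digit, outside the 250.X0/250.X2 expansion
  expect_true(is.na(first_type2_code_date(mk_dx("2001-04-02", "250.01"), cfg)))
  # pre-window codes do not count, and make the patient ineligible
  dec <- evaluate_case(pt, mk_dx("1994-12-31", "250.00"), no_labs, no_meds, cfg)
  expect_identical(dec$status, "ineligible")
  expect_true("prestudy_diabetes_related_code" %in% dec$reasons)
})

test_that("onset is the earlier of first code and second abnormal lab", {
  expect_identical(assign_onset_date(as.Date("2002-06-01"), as.Date("2001-09-01")),
                   as.Date("2001-09-01"))
  expect_identical(assign_onset_date(as.Date("2002-06-01"), as.Date("2002-06-01")),
                   as.Date("2002-06-01"))
  expect_identical(assign_onset_date(as.Date("2002-06-01"), as.Date("2002-08-15")),
                   as.Date("2002-06-01"))
  expect_error(assign_onset_date(as.Date("2002-06-01"), as.Date(NA)), "both dates")
})

test_that("the case criteria fire in order with recorded reasons", {
  cfg <- default_cfg
  dx <- mk_dx("2002-06-01", "250.00")
  labs <- mk_labs(c("2001-03-01", "2001-09-01", "2000-07-01"),
                  rep("hba1c", 3), c(7.0, 7.2, 5.5))

  dec <- evaluate_case(pt, dx, labs, no_meds, cfg)
  expect_identical(dec$status, "case")
  expect_identical(dec$onset_date, as.Date("2001-09-01"))
  expect_identical(dec$first_t2d_code_date, as.Date("2002-06-01"))
  expect_identical(dec$second_abnormal_date, as.Date("2001-09-01"))
  expect_length(dec$reasons, 0)

  # an additional abnormal more than 3 years before the code excludes
  labs2 <- rbind(labs, mk_labs("1998-01-01", "hba1c", 7.5))
  dec2 <- evaluate_case(pt, dx, labs2, no_meds, cfg)
  expect_identical(dec2$status, "excluded")
  expect_true("abnormal_lab_gt_3y_before_code" %in% dec2$reasons)

  # a type 1 code within a year of the first type 2 code excludes
  dx3 <- rbind(dx, mk_dx("2002-12-01", "250.01"))
  dec3 <- evaluate_case(pt, dx3, labs, no_meds, cfg)
  expect_identical(dec3$status, "excluded")
  expect_true("type1_within_precedence" %in% dec3$reasons)

  # medication starting > 30 days before the assigned onset excludes
  dec4 <- evaluate_case(pt, dx, labs, mk_meds("metformin", "2001-06-01"), cfg)
  expect_identical(dec4$status, "excluded")
  expect_true("med_before_onset" %in% dec4$reasons)
  # a start between onset and code is admissible against the onset anchor
  # but excluded when the exclusion is anchored at the code date
  cfg_code <- phenotype_config(med_anchor = "code")
  late_med <- mk_meds("metformin", "2002-03-01")
  expect_identical(evaluate_case(pt, dx, labs, late_med, cfg)$status, "case")
  expect_identical(evaluate_case(pt, dx, labs, late_med, cfg_code)$status,
                   "excluded")

  # no events at all: ineligible via the control path
  dec5 <- evaluate_case(pt, no_dx, no_labs, no_meds, cfg)
  expect_identical(dec5$status, "ineligible")
})

test_that("control definition requires a normal lab and no diabetes evidence", {
  cfg <- default_cfg
  ok <- evaluate_control(pt, mk_dx("2003-02-01", "401.9"),
                         mk_labs("2003-02-01", "hba1c", 5.6), no_meds, cfg)
  expect_identical(ok$status, "control")

  no_lab <- evaluate_control(pt, mk_dx("2003-02-01", "401.9"), no_labs, no_meds, cfg)
  expect_identical(no_lab$status, "excluded")
  expect_identical(no_lab$reasons, "no_normal_lab")

  med <- evaluate_control(pt, no_dx, mk_labs("2003-02-01", "hba1c", 5.6),
                          mk_meds("metformin", "2005-01-01"), cfg)
  expect_identical(med$status, "excluded")
  expect_true("diabetes_medication" %in% med$reasons)

  # abnormal labs do not exclude controls unless the optional rule is on
  ctl_labs <- mk_labs(c("2002-01-01", "2003-01-01", "2004-01-01"),
                      rep("hba1c", 3), c(5.6, 7.0, 7.1))
  expect_identical(evaluate_control(pt, no_dx, ctl_labs, no_meds, cfg)$status,
                   "control")
  cfg_strict <- phenotype_config(exclude_probable_undiagnosed = TRUE)
  strict <- evaluate_control(pt, no_dx, ctl_labs, no_meds, cfg_strict)
  expect_identical(strict$status, "excluded")
  expect_true("probable_undiagnosed_diabetes" %in% strict$reasons)
})

test_that("evaluate_case agrees with the brute-force oracle on random patients", {
  cfg <- default_cfg
  set.seed(2024)
  for (i in 1:1500) {
    rp <- random_patient(10)
    dec <- evaluate_case(rp$patient, rp$dx, rp$labs, rp$meds, cfg)
    ora <- oracle_decision(rp$patient$birth_date, rp$dx, rp$labs, rp$meds, cfg)
    expect_decision_matches(dec, ora, info = paste("iteration", i))
  }
})

test_that("extra normal labs never break a case; early abnormals never create one", {
  cfg <- default_cfg
  set.seed(99)
  # structured fixtures that satisfy the case criteria by construction
  for (i in 1:100) {
    code <- as.Date("1999-01-01") + sample.int(3600, 1)
    abn1 <- code - sample(200:1000, 1)
    abn2 <- abn1 + sample(30:200, 1)
    norm <- code - sample(1:1000, 1)
    dx <- data.frame(date = code, code = "250.00", is_well_visit = FALSE)
    labs <- data.frame(date = c(abn1, abn2, norm), analyte = "hba1c",
                       value = c(7.0, 7.1, 5.5))
    dec <- evaluate_case(pt, dx, labs, no_meds, cfg)
    expect_identical(dec$status, "case")
    # an extra normal lab inside the window never breaks the case
    extra <- data.frame(date = code - sample(1:1000, 1), analyte = "hba1c",
                        value = 5.2)
    expect_identical(evaluate_case(pt, dx, rbind(labs, extra), no_meds, cfg)$status,
                     "case")
    # an extra abnormal before code - onset_window always breaks it
    early <- data.frame(date = code - cfg$onset_window - sample(1:2000, 1),
                        analyte = "hba1c", value = 9.0)
    expect_identical(evaluate_case(pt, dx, rbind(labs, early), no_meds, cfg)$status,
                     "excluded")
  }
  # ...and on unconstrained random patients, early abnormals never create a case
  checked_noncase <- 0
  for (i in 1:300) {
    rp <- random_patient(8)
    dec <- evaluate_case(rp$patient, rp$dx, rp$labs, rp$meds, cfg)
    if (dec$status != "case" && !is.na(dec$first_t2d_code_date)) {
      early <- data.frame(date = dec$first_t2d_code_date - cfg$onset_window - 50,
                          analyte = "hba1c", value = 9.0)
      dec2 <- evaluate_case(rp$patient, rp$dx, rbind(rp$labs, early), rp$meds, cfg)
      expect_false(dec2$status == "case")
      checked_noncase <- checked_noncase + 1
    }
  }
  expect_gt(checked_noncase, 5)
})

test_that("population evaluation partitions patients and bounds case onsets", {
  sim <- small_sim()
  dec <- evaluate_population(sim$dataset)
  expect_identical(sort(dec$patient_id), sort(sim$dataset$patients$patient_id))
  expect_true(all(dec$status %in% c("case", "control", "excluded", "ineligible")))
  cases <- dec[dec$status == "case", ]
  expect_true(all(cases$onset_date <= cases$first_t2d_code_date))
  expect_true(all(cases$onset_date >=
                    cases$first_t2d_code_date - default_cfg$onset_window))
  expect_true(all(cases$reasons == ""))
  # determinism: identical streams yield identical decisions
  expect_identical(dec, evaluate_population(sim$dataset))
})
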