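yearly_encounters <- function(years, month_day = "-06-01") {
  as.Date(paste0(years, month_day))
}

test_that("gap censoring matches the hand-traced rules", {
  fu <- as.Date("2011-12-31")
  # no gaps: window runs from the first encounter to the follow-up end
  enc <- yearly_encounters(1990:2011)
  w <- censored_window(enc, as.Date("2002-05-01"), fu)
  expect_identical(w$lookback_start, as.Date("1990-06-01"))
  expect_identical(w$followup_end, fu)

  # 4 empty years before the reference: look-back starts Jan 1 after the gap
  enc2 <- yearly_encounters(c(1990:1995, 2000:2011))
  w2 <- censored_window(enc2, as.Date("2002-05-01"), fu)
  expect_identical(w2$lookback_start, as.Date("2000-01-01"))
  expect_identical(w2$followup_end, fu)

  # 4 empty years after the reference: follow-up censored before the gap
  enc3 <- yearly_encounters(c(1990:2004, 2009:2011))
  w3 <- censored_window(enc3, as.Date("2002-05-01"), fu)
  expect_identical(w3$followup_end, as.Date("2004-12-31"))

  # a 3-year hole is not a gap
  enc4 <- yearly_encounters(c(1990:1995, 1999:2011))
  expect_identical(censored_window(enc4, as.Date("2002-05-01"), fu)$lookback_start,
                   as.Date("1990-06-01"))

  # reference date with no coverage is an error
  expect_error(censored_window(as.Date(character()), as.Date("2002-05-01"), fu),
               "no encounters")
  expect_error(censored_window(yearly_encounters(2005:2011),
                               as.Date("2002-05-01"), fu), "outside")
  expect_error(censored_window(yearly_encounters(c(1990:1995, 2004:2011)),
                               as.Date("1999-05-01"), fu), "gap")
})

test_that("gap censoring agrees with the year-occupancy oracle and is idempotent", {
  fu <- as.Date("2011-12-31")
  set.seed(31)
  for (i in 1:300) {
    yrs <- sort(sample(1988:2011, sample(5:20, 1)))
    enc <- yearly_encounters(yrs)
    cand <- yrs[yrs >= 1995 & yrs <= 2009]
    if (length(cand) == 0) next
    ref <- as.Date(sprintf("%d-07-15", cand[sample.int(length(cand), 1)]))
    w <- tryCatch(censored_window(enc, ref, fu), error = function(e) NULL)
    o <- oracle_window(enc, ref, fu)
    if (is.null(o)) {
      expect_null(w)
    } else {
      expect_false(is.null(w))
      expect_identical(w$lookback_start, o$lookback_start)
      expect_identical(w$followup_end, o$followup_end)
      # idempotence: re-censoring at the censored follow-up end is a fixed point
      w2 <- censored_window(enc, ref, w$followup_end)
      expect_identical(w2$lookback_start, w$lookback_start)
      expect_identical(w2$followup_end, w$followup_end)
    }
  }
})

test_that("engagement requires a non-diabetes contact in the prior three years", {
  rel <- default_cfg$code_sets$diabetes_related
  ref <- as.Date("2002-05-01")
  expect_true(check_engagement(mk_dx("2000-11-03", "401.9"), ref, rel))
  # diabetes codes alone do not count
  expect_false(check_engagement(mk_dx(c("2000-11-03", "2001-02-01"),
                                      c("250.00", "362.01")), ref, rel))
  # a well-visit counts even if the code is diabetes-related
  expect_true(check_engagement(mk_dx("2000-11-03", "250.00", well = TRUE), ref, rel))
  # same calendar year as the reference does not count under the strict reading
  expect_false(check_engagement(mk_dx("2002-01-15", "401.9"), ref, rel))
  expect_true(check_engagement(mk_dx("2002-01-15", "401.9"), ref, rel,
                               include_reference_year = TRUE))
  # too early does not count
  expect_false(check_engagement(mk_dx("1998-12-31", "401.9"), ref, rel))
})

test_that("stratum keys combine birth category, smoking, MESA and period", {
  cuts <- c(1925, 1935, 1945, 1955)
  p <- list(birth_date = as.Date("1931-01-01"), smoking_ever = TRUE,
            mesa_resident_ever = FALSE)
  s <- stratify(p, as.Date("1999-12-31"), cuts)
  expect_equal(s$birth_category, 2)
  expect_identical(s$reference_period, "1995-1999")
  expect_identical(stratify(p, as.Date("2000-01-01"), cuts)$reference_period,
                   "2000-2004")
  p2 <- p; p2$smoking_ever <- FALSE
  expect_false(stratify(p, as.Date("2000-01-01"), cuts)$key ==
                 stratify(p2, as.Date("2000-01-01"), cuts)$key)
  expect_error(stratify(p, as.Date("2010-03-01"), cuts), "1995-2009")
  expect_error(stratify(p, as.Date("2000-01-01"), cuts[1:3]), "4 interior")
})

test_that("frequency matching samples min(ratio*c, available) per stratum", {
  cases <- data.frame(patient_id = "C1", stratum_key = "b1|smoke1|mesa0|1995-1999",
                      demo_key = "b1|smoke1|mesa0")
  ctrl <- data.frame(patient_id = paste0("K", 1:10),
                     demo_key = "b1|smoke1|mesa0")
  fm <- frequency_match(cases, ctrl, 5, seed = 3)
  expect_equal(nrow(fm$selected), 5)
  expect_equal(nrow(fm$shortfalls), 0)
  expect_equal(fm$achieved_ratio, 5)

  cases2 <- data.frame(patient_id = c("C1", "C2"),
                       stratum_key = "b1|smoke1|mesa0|1995-1999",
                       demo_key = "b1|smoke1|mesa0")
  fm2 <- frequency_match(cases2, ctrl[1:7, , drop = FALSE], 5, seed = 3)
  expect_equal(nrow(fm2$selected), 7)
  expect_equal(fm2$shortfalls$wanted - fm2$shortfalls$taken, 3)

  # determinism under the seed; a different seed gives a different draw
  big_ctrl <- data.frame(patient_id = paste0("K", 1:40),
                         demo_key = "b1|smoke1|mesa0")
  a <- frequency_match(cases, big_ctrl, 5, seed = 11)
  b <- frequency_match(cases, big_ctrl, 5, seed = 11)
  expect_identical(a$selected, b$selected)
  d <- frequency_match(cases, big_ctrl, 5, seed = 12)
  expect_false(identical(a$selected$patient_id, d$selected$patient_id))
})

test_that("assigned reference dates come from the stratum's case onset distribution", {
  key <- "b1|smoke1|mesa0|2000-2004"
  one_case <- data.frame(patient_id = "C1", stratum_key = key,
                         onset_date = as.Date("2003-03-03"))
  ctrl <- data.frame(patient_id = paste0("K", 1:8), stratum_key = key)
  asg <- assign_reference_dates(ctrl, one_case, seed = 5)
  expect_true(all(asg$reference_date == as.Date("2003-03-03")))
  expect_true(all(asg$matched_from_case == "C1"))

  two_cases <- data.frame(patient_id = c("C1", "C2"), stratum_key = key,
                          onset_date = as.Date(c("2001-01-01", "2004-05-05")))
  many <- data.frame(patient_id = sprintf("K%05d", 1:10000), stratum_key = key)
  asg2 <- assign_reference_dates(many, two_cases, seed = 5)
  share <- mean(asg2$reference_date == as.Date("2001-01-01"))
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(share - 0.5), 3 * se)
  expect_true(all(asg2$reference_date %in% two_cases$onset_date))

  orphan <- data.frame(patient_id = "K1", stratum_key = "b9|smoke0|mesa0|1995-1999")
  expect_error(assign_reference_dates(orphan, two_cases, seed = 1), "zero cases")
})

test_that("cohort construction preserves strata, the ratio bound and the 60-day rule", {
  sim <- small_sim()
  dec <- evaluate_population(sim$dataset)
  cfg <- run_config(seed = 17)
  b <- build_cohort(sim$dataset, dec, cfg)
  co <- b$cohort
  expect_gt(sum(co$arm == "diabetes"), 0)
  expect_lte(b$achieved_ratio, cfg$ratio)

  # every control's stratum equals the stratum of the case that supplied
  # its reference date
  ctrl <- co[co$arm == "no_diabetes", ]
  case <- co[co$arm == "diabetes", ]
  m <- merge(ctrl, case, by.x = "matched_from_case", by.y = "patient_id",
             suffixes = c("", ".case"))
  expect_equal(nrow(m), nrow(ctrl))
  expect_true(all(m$birth_category == m$birth_category.case))
  expect_true(all(m$smoking_ever == m$smoking_ever.case))
  expect_true(all(m$mesa_ever == m$mesa_ever.case))
  expect_true(all(m$reference_period == m$reference_period.case))
  expect_true(all(m$reference_date == m$reference_date.case))

  # minimum post-reference observation
  expect_true(all(as.numeric(co$followup_end - co$reference_date) >=
                    cfg$min_observation_days))
  expect_true(all(co$lookback_start <= co$reference_date))

  # reruns are identical under the same seed
  b2 <- build_cohort(sim$dataset, dec, cfg)
  expect_identical(b$cohort, b2$cohort)
  expect_identical(b$attrition, b2$attrition)
})
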