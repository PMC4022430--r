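win <- structure(list(lookback_start = as.Date("1996-01-01"),
                      reference_date = as.Date("2003-06-01"),
                      followup_end = as.Date("2009-12-31")),
                 class = "observation_window")
sites <- with(default_cfg$code_sets,
              list(breast = breast_cancer, prostate = prostate_cancer,
                   colon = colon_cancer))

test_that("cancer needs two in-window codes and dates to the first one", {
  expect_equal(nrow(ascertain_cancer(mk_dx("2004-01-01", "174.9"), sites, win)), 0)

  ca <- ascertain_cancer(mk_dx(c("2004-01-01", "2004-06-01"), "174.9"), sites, win)
  expect_equal(ca$site, "breast")
  expect_identical(ca$diagnosis_date, as.Date("2004-01-01"))
  expect_equal(ca$n_codes, 2)

  # one of the two codes outside the censored window does not count
  expect_equal(nrow(ascertain_cancer(mk_dx(c("1995-06-01", "2004-06-01"), "174.9"),
                                     sites, win)), 0)
  # ...but enlarging the window can only add diagnoses
  wide <- win; wide$lookback_start <- as.Date("1990-01-01")
  expect_equal(nrow(ascertain_cancer(mk_dx(c("1995-06-01", "2004-06-01"), "174.9"),
                                     sites, wide)), 1)
  # optional minimum separation
  close2 <- mk_dx(c("2004-01-01", "2004-01-10"), "185")
  expect_equal(nrow(ascertain_cancer(close2, sites, win)), 1)
  expect_equal(nrow(ascertain_cancer(close2, sites, win, min_separation_days = 30)), 0)
})

test_that("comorbidity flags use the two-code rule and Charlson weights", {
  cs <- default_cfg$code_sets
  none <- comorbidity_profile(no_dx, win, cs)
  expect_false(any(unlist(none[names(charlson_weights())])))
  expect_equal(none$charlson_modified, 0)

  mi <- comorbidity_profile(mk_dx(c("2000-01-01", "2001-01-01"),
                                  c("410.01", "412")), win, cs)
  expect_true(mi$myocardial_infarction)
  expect_equal(mi$charlson_modified, 1)

  # one code each for two conditions scores nothing
  split2 <- comorbidity_profile(mk_dx(c("2000-01-01", "2001-01-01"),
                                      c("410.01", "585")), win, cs)
  expect_equal(split2$charlson_modified, 0)

  # renal disease carries weight 2
  renal <- comorbidity_profile(mk_dx(c("2000-01-01", "2001-01-01"),
                                     c("585", "586")), win, cs)
  expect_true(renal$renal_disease)
  expect_equal(renal$charlson_modified, 2)
})

test_that("visit frequency uses half-open 730-day windows and Table-style bins", {
  ref <- as.Date("2003-06-01")
  vf0 <- visit_frequency(as.Date(character()), ref)
  expect_identical(c(vf0$pre_bin, vf0$post_bin), c("0-5", "0-5"))

  many_post <- ref + seq_len(21) * 10
  expect_identical(visit_frequency(many_post, ref)$post_bin, ">20")
  expect_identical(visit_frequency(ref + (1:11) * 10, ref)$post_bin, "11-20")
  expect_identical(visit_frequency(ref - (1:6) * 10, ref)$pre_bin, "6-10")

  # an encounter exactly on the reference date belongs to "after"
  on_ref <- visit_frequency(ref, ref)
  expect_equal(on_ref$pre_n, 0)
  expect_equal(on_ref$post_n, 1)
})

test_that("medication exposure unions intervals and respects the window", {
  none <- medication_exposure(mk_meds(), win)
  expect_false(any(none$ever))

  met <- data.frame(drug_class = "metformin", start_date = as.Date("2003-01-01"),
                    stop_date = as.Date("2003-12-31"))
  me <- medication_exposure(met, win)
  expect_equal(me$days_exposed[me$drug_class == "metformin"], 364)

  # overlapping intervals are not double counted; oracle = day grid
  ins <- data.frame(drug_class = "insulin",
                    start_date = as.Date(c("2004-01-01", "2004-03-01", "2005-01-01")),
                    stop_date = as.Date(c("2004-06-30", "2004-09-30", "2005-03-31")))
  got <- medication_exposure(ins, win)$days_exposed[1]
  grid <- unique(unlist(mapply(function(a, b) seq(a, b - 1, by = "1 day"),
                               ins$start_date, ins$stop_date, SIMPLIFY = FALSE)))
  expect_equal(got, length(grid))

  # open-ended records are truncated at the window end, never beyond it
  open <- data.frame(drug_class = "sulfonylurea",
                     start_date = as.Date("2009-01-01"), stop_date = as.Date(NA))
  so <- medication_exposure(open, win)
  expect_equal(so$days_exposed[so$drug_class == "sulfonylurea"],
               as.numeric(win$followup_end - as.Date("2009-01-01")))
  win_len <- as.numeric(win$followup_end - win$lookback_start)
  expect_true(all(medication_exposure(ins, win)$days_exposed <= win_len))
})

test_that("descriptive summary percentages are coherent by arm", {
  sim <- small_sim()
  dec <- evaluate_population(sim$dataset)
  b <- build_cohort(sim$dataset, dec, run_config(seed = 17))
  cov <- compute_covariates(sim$dataset, b$cohort, run_config())
  s <- descriptive_summary(b$cohort, cov, sim$dataset)

  expect_equal(s$achieved_ratio, round(s$n_controls / s$n_cases, 1))
  # within each exhaustive categorical variable and arm the percentages sum to 100
  tab <- s$table
  for (v in c("gender", "age_group", "smoking", "reference_period",
              "mesa_residency", "visits_pre", "visits_post")) {
    for (a in c("diabetes", "no_diabetes")) {
      tot <- sum(tab$pct[tab$variable == v & tab$arm == a])
      expect_lt(abs(tot - 100), 0.11)
    }
  }

  # a single-arm cohort zeroes the other arm's column
  case_only <- b$cohort[b$cohort$arm == "diabetes", ]
  s1 <- descriptive_summary(case_only, cov, sim$dataset)
  expect_equal(s1$n_controls, 0)
  expect_true(all(s1$table$n[s1$table$arm == "no_diabetes"] == 0))
})
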