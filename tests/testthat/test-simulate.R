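test_that("simulation is deterministic under a fixed seed", {
  p <- simulation_params(n_patients = 300)
  a <- simulate_population(p, seed = 8)
  b <- simulate_population(p, seed = 8)
  expect_identical(a$truth, b$truth)
  for (s in c("patients", "diagnoses", "labs", "medications", "encounters", "bmi")) {
    expect_identical(as.data.frame(a$dataset[[s]]), as.data.frame(b$dataset[[s]]),
                     info = s)
  }
  d <- simulate_population(p, seed = 9)
  expect_false(identical(as.data.frame(a$dataset$labs), as.data.frame(d$dataset$labs)))
})

test_that("generated datasets satisfy the container invariants", {
  for (s in c(2, 77)) {
    sim <- simulate_population(simulation_params(n_patients = 400), seed = s)
    expect_equal(nrow(validate_emr(sim$dataset)), 0, info = paste("seed", s))
    expect_true(all(sim$truth$true_status %in% c("t2d", "t1d", "none")))
    expect_identical(is.na(sim$truth$true_onset_date),
                     sim$truth$true_status != "t2d")
  }
})

test_that("a world without type 2 diabetes yields no cases", {
  p <- simulation_params(n_patients = 600, fraction_true_t2d = 0,
                         fraction_type1_distractors = 0, miscode_prob = 0)
  sim <- simulate_population(p, seed = 4)
  expect_equal(sum(sim$truth$true_status == "t2d"), 0)
  dec <- evaluate_population(sim$dataset)
  expect_equal(sum(dec$status == "case"), 0)
})

test_that("dense visits and universal testing detect essentially all accrued cases", {
  # the convergence property is stated for the noise-free limit: with
  # assay noise present, denser testing also surfaces more false early
  # abnormals
  p <- simulation_params(n_patients = 400, fraction_true_t2d = 0.5,
                         fraction_type1_distractors = 0, miscode_prob = 0,
                         visit_rate_t2d = 12, visit_rate_other = 12,
                         lab_test_prob_per_visit = 1,
                         measurement_noise_sd = 0.01,
                         fasting_noise_sd = 0.5, random_noise_sd = 0.5)
  sim <- simulate_population(p, seed = 21)
  dec <- evaluate_population(sim$dataset)
  m <- merge(dec, sim$truth, by = "patient_id")
  # onsets late in the accrual window can be coded after it closes, so
  # judge detection on onsets with room for the coding lag
  evaluable <- m$true_status == "t2d" &
    m$true_onset_date <= p$study_end - 730
  expect_gt(mean(m$status[evaluable] == "case"), 0.97)
  oe <- onset_error_distribution(dec, sim$truth)
  # with near-continuous testing the assigned onset hugs the true onset
  expect_gt(oe$prop_within, 0.85)
})

test_that("onset error handles the exact and the disjoint extremes", {
  dec <- data.frame(patient_id = c("A", "B"), status = "case",
                    onset_date = as.Date(c("2001-01-01", "2005-06-07")))
  tru <- data.frame(patient_id = c("A", "B"), true_status = "t2d",
                    true_onset_date = as.Date(c("2001-01-01", "2005-06-07")))
  expect_equal(onset_error_distribution(dec, tru)$prop_within, 1.0)

  tru2 <- data.frame(patient_id = "Z", true_status = "t2d",
                     true_onset_date = as.Date("2001-01-01"))
  expect_error(onset_error_distribution(dec, tru2), "no evaluable")
})

test_that("detection sensitivity rises with the testing rate", {
  sens_at <- function(prob) {
    p <- simulation_params(n_patients = 1500, lab_test_prob_per_visit = prob,
                           measurement_noise_sd = 0.01,
                           fasting_noise_sd = 0.5, random_noise_sd = 0.5)
    sim <- simulate_population(p, seed = 12)
    dec <- evaluate_population(sim$dataset)
    m <- merge(dec, sim$truth, by = "patient_id")
    mean(m$status[m$true_status == "t2d"] == "case")
  }
  s <- vapply(c(0.1, 0.5, 1.0), sens_at, numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("onset-dating accuracy degrades with the coding lag", {
  prop_at <- function(lag) {
    p <- simulation_params(n_patients = 1500, coding_lag_mean_days = lag)
    sim <- simulate_population(p, seed = 13)
    onset_error_distribution(evaluate_population(sim$dataset), sim$truth)$prop_within
  }
  expect_gt(prop_at(60), prop_at(540))
})
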