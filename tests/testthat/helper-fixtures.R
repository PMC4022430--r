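# Shared fixture builders: everything is generated in code at test time.

default_cfg <- phenotype_config()

mk_patient <- function(id = "P1", birth = "1950-06-15",
                       gender = "male", smoking = TRUE, mesa = FALSE) {
  data.frame(patient_id = id, birth_date = as.Date(birth), gender = gender,
             smoking_ever = smoking, mesa_resident_ever = mesa, insured = TRUE)
}

mk_dx <- function(dates = character(), codes = character(), well = FALSE, id = "P1") {
  data.frame(patient_id = rep(id, length.out = length(dates)),
             date = as.Date(dates), code = codes,
             is_well_visit = rep(well, length.out = length(dates)))
}

mk_labs <- function(dates = character(), analytes = character(), values = numeric(),
                    id = "P1") {
  data.frame(patient_id = rep(id, length.out = length(dates)),
             date = as.Date(dates), analyte = analytes, value = values)
}

mk_meds <- function(classes = character(), starts = character(), id = "P1") {
  data.frame(patient_id = rep(id, length.out = length(classes)),
             drug_class = classes, start_date = as.Date(starts))
}

no_dx <- mk_dx()
no_labs <- mk_labs()
no_meds <- mk_meds()

# A small but complete simulated world reused across tests (cheap: ~1 s).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_population(simulation_params(n_patients = 800), seed = 424)
    }
    cache
  }
})
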