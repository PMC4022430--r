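#' Longitudinal EMR dataset container
#'
#' An `emr_dataset` bundles the per-patient event streams the phenotyping
#' pipeline consumes: demographics, diagnosis events (ICD-9), glycemic
#' laboratory results, antidiabetic medication records, healthcare
#' encounters and BMI measurements, together with the study window and the
#' follow-up end date. All streams are kept sorted by patient and date;
#' codes are normalized to canonical dotted ICD-9 at construction.
#'
#' @param patients data.frame with columns `patient_id`, `birth_date`,
#'   `gender` (`"male"`/`"female"`), `smoking_ever`, `mesa_resident_ever`
#'   (logical), and optionally `insured` (logical).
#' @param diagnoses data.frame `patient_id`, `date`, `code`,
#'   `is_well_visit` (logical, optional — defaults to `FALSE`).
#' @param labs data.frame `patient_id`, `date`, `analyte` (one of
#'   `"hba1c"`, `"fasting_glucose"`, `"random_glucose"`), `value`
#'   (percent for HbA1c, mg/dL for glucose).
#' @param medications data.frame `patient_id`, `drug_class` (one of
#'   `"insulin"`, `"metformin"`, `"sulfonylurea"`, `"other_antidiabetic"`,
#'   `"non_diabetes"`), `start_date`, `stop_date` (may be `NA`, ongoing).
#' @param encounters data.frame `patient_id`, `date`, `kind`.
#' @param bmi data.frame `patient_id`, `date`, `bmi`.
#' @param study_window Length-2 `Date` vector: start and end of the
#'   incidence accrual window.
#' @param followup_end Last date of follow-up observation.
#' @return Object of class `emr_dataset`.
#' @seealso [read_emr_dir()], [write_emr_dir()], [validate_emr()]
#' @export
emr_dataset <- function(patients,
                        diagnoses = empty_stream("diagnoses"),
                        labs = empty_stream("labs"),
                        medications = empty_stream("medications"),
                        encounters = empty_stream("encounters"),
                        bmi = empty_stream("bmi"),
                        study_window = as.Date(c("1995-01-01", "2009-12-31")),
                        followup_end = as.Date("2011-12-31")) {
  patients <- data.table::as.data.table(patients)
  req <- c("patient_id", "birth_date", "gender", "smoking_ever", "mesa_resident_ever")
  miss <- setdiff(req, names(patients))
  if (length(miss) > 0) stopf("patients: missing column(s) %s", paste(miss, collapse = ", "))
  if (anyDuplicated(patients$patient_id)) stopf("patients: duplicated patient_id")
  patients[, birth_date := as_emr_date(birth_date)]
  if (!"insured" %in% names(patients)) patients[, insured := NA]
  data.table::setkey(patients, patient_id)

  diagnoses <- coerce_stream(diagnoses, c("patient_id", "date", "code"))
  if (!"is_well_visit" %in% names(diagnoses)) diagnoses[, is_well_visit := FALSE]
  diagnoses[, code := normalize_icd9(code)]
  labs <- coerce_stream(labs, c("patient_id", "date", "analyte", "value"))
  medications <- data.table::as.data.table(medications)
  for (col in c("patient_id", "drug_class", "start_date")) {
    if (!col %in% names(medications)) stopf("medications: missing column %s", col)
  }
  medications[, start_date := as_emr_date(start_date)]
  if (!"stop_date" %in% names(medications)) medications[, stop_date := as.Date(NA)]
  medications[, stop_date := as_emr_date(stop_date)]
  data.table::setorder(medications, patient_id, start_date)
  encounters <- coerce_stream(encounters, c("patient_id", "date", "kind"))
  encounters <- unique(encounters, by = c("patient_id", "date", "kind"))
  bmi <- coerce_stream(bmi, c("patient_id", "date", "bmi"))

  structure(list(
    patients = patients, diagnoses = diagnoses, labs = labs,
    medications = medications, encounters = encounters, bmi = bmi,
    study_window = as_emr_date(study_window), followup_end = as_emr_date(followup_end)
  ), class = "emr_dataset")
}

empty_stream <- function(what) {
  switch(what,
    diagnoses = data.table::data.table(patient_id = character(), date = as.Date(character()),
                                       code = character(), is_well_visit = logical()),
    labs = data.table::data.table(patient_id = character(), date = as.Date(character()),
                                  analyte = character(), value = numeric()),
    medications = data.table::data.table(patient_id = character(), drug_class = character(),
                                         start_date = as.Date(character()),
                                         stop_date = as.Date(character())),
    encounters = data.table::data.table(patient_id = character(), date = as.Date(character()),
                                        kind = character()),
    bmi = data.table::data.table(patient_id = character(), date = as.Date(character()),
                                 bmi = numeric())
  )
}

coerce_stream <- function(x, cols) {
  x <- data.table::as.data.table(x)
  miss <- setdiff(cols, names(x))
  if (length(miss) > 0) stopf("stream: missing column(s) %s", paste(miss, collapse = ", "))
  x[, date := as_emr_date(date)]
  data.table::setorder(x, patient_id, date)
  x
}

#' @export
print.emr_dataset <- function(x, ...) {
  cat(sprintf("<emr_dataset> %d patients; study window %s .. %s; follow-up through %s\n",
              nrow(x$patients), x$study_window[1], x$study_window[2], x$followup_end))
  for (s in c("diagnoses", "labs", "medications", "encounters", "bmi")) {
    cat(sprintf("  %-12s %d rows\n", s, nrow(x[[s]])))
  }
  invisible(x)
}

#' Integrity check of an EMR dataset
#'
#' Enumerates events whose `patient_id` has no demographics row
#' (`orphan_event`), streams not sorted ascending by date within patient
#' (`unsorted_stream`), and events dated before the patient's birth
#' (`event_before_birth`). A clean dataset yields a zero-row table.
#'
#' @param dataset An [emr_dataset()].
#' @return data.frame with columns `kind`, `stream`, `patient_id`, `detail`.
#' @export
validate_emr <- function(dataset) {
  stopifnot(inherits(dataset, "emr_dataset"))
  findings <- list()
  pid <- dataset$patients$patient_id
  births <- dataset$patients[, .(patient_id, birth_date)]
  for (s in c("diagnoses", "labs", "medications", "encounters", "bmi")) {
    st <- dataset[[s]]
    if (nrow(st) == 0) next
    datecol <- if (s == "medications") "start_date" else "date"
    orphan <- unique(st$patient_id[!st$patient_id %in% pid])
    for (p in orphan) {
      findings[[length(findings) + 1L]] <- data.frame(
        kind = "orphan_event", stream = s, patient_id = p,
        detail = "event for unknown patient_id")
    }
    d <- st[[datecol]]
    unsorted <- st$patient_id[c(FALSE, diff(d) < 0 & st$patient_id[-1] == st$patient_id[-nrow(st)])]
    for (p in unique(unsorted)) {
      findings[[length(findings) + 1L]] <- data.frame(
        kind = "unsorted_stream", stream = s, patient_id = p,
        detail = "dates not ascending")
    }
    m <- merge(st[, c("patient_id", datecol), with = FALSE], births, by = "patient_id")
    early <- unique(m$patient_id[m[[datecol]] < m$birth_date])
    for (p in early) {
      findings[[length(findings) + 1L]] <- data.frame(
        kind = "event_before_birth", stream = s, patient_id = p,
        detail = "event dated before birth_date")
    }
  }
  if (length(findings) == 0) {
    return(data.frame(kind = character(), stream = character(),
                      patient_id = character(), detail = character()))
  }
  do.call(rbind, findings)
}

# ---- delimited-file IO -----------------------------------------------------

#' Default file/column schema for EMR directories
#'
#' Maps each logical stream to its CSV file name and column names, so
#' source extracts with different headers can be loaded by supplying a
#' modified schema (or a YAML file with the same structure).
#' @return Nested named list.
#' @export
emr_schema <- function() {
  list(
    patients = list(file = "patients.csv",
                    columns = c(patient_id = "patient_id", birth_date = "birth_date",
                                gender = "gender", smoking_ever = "smoking_ever",
                                mesa_resident_ever = "mesa_resident_ever",
                                insured = "insured")),
    diagnoses = list(file = "diagnoses.csv",
                     columns = c(patient_id = "patient_id", date = "date",
                                 code = "code", is_well_visit = "is_well_visit")),
    labs = list(file = "labs.csv",
                columns = c(patient_id = "patient_id", date = "date",
                            analyte = "analyte", value = "value")),
    medications = list(file = "medications.csv",
                       columns = c(patient_id = "patient_id", drug_class = "drug_class",
                                   start_date = "start_date", stop_date = "stop_date")),
    encounters = list(file = "encounters.csv",
                      columns = c(patient_id = "patient_id", date = "date", kind = "kind")),
    bmi = list(file = "bmi.csv",
               columns = c(patient_id = "patient_id", date = "date", bmi = "bmi"))
  )
}

VALID_ANALYTES <- c("hba1c", "fasting_glucose", "random_glucose")
VALID_DRUG_CLASSES <- c("insulin", "metformin", "sulfonylurea",
                        "other_antidiabetic", "non_diabetes")

#' Read an EMR dataset from a directory of CSV files
#'
#' Expects the six delimited files named in the schema (UTF-8, header row,
#' ISO-8601 dates) plus an optional `meta.yaml` carrying the study window
#' and follow-up end written by [write_emr_dir()]. Rows violating stream
#' invariants (unparseable dates, non-positive lab values, unknown
#' analytes or drug classes, events for unknown patients) are rejected
#' row-by-row and reported in the `rejected` attribute of the result;
#' missing files or columns are errors.
#'
#' @param dir Directory path.
#' @param schema Schema as from [emr_schema()].
#' @param study_window,followup_end Overrides for the values in
#'   `meta.yaml` (required if that file is absent).
#' @param quiet Suppress per-row rejection messages.
#' @return An [emr_dataset()] with attribute `rejected` (data.frame:
#'   `file`, `row`, `reason`).
#' @export
read_emr_dir <- function(dir, schema = emr_schema(),
                         study_window = NULL, followup_end = NULL,
                         quiet = FALSE) {
  meta_path <- file.path(dir, "meta.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    study_window <- study_window %||% as.Date(c(meta$study_start, meta$study_end))
    followup_end <- followup_end %||% as.Date(meta$followup_end)
  }
  if (is.null(study_window) || is.null(followup_end)) {
    stopf("no meta.yaml in %s: study_window and followup_end must be supplied", dir)
  }

  rejected <- list()
  note <- function(file, rows, reason) {
    if (length(rows) == 0) return()
    if (!quiet) message(sprintf("%s: rejected %d row(s): %s", file, length(rows), reason))
    rejected[[length(rejected) + 1L]] <<- data.frame(file = file, row = rows, reason = reason)
  }

  read_one <- function(entry) {
    path <- file.path(dir, entry$file)
    if (!file.exists(path)) stopf("missing input file: %s", path)
    dt <- data.table::fread(path, colClasses = "character", na.strings = c("", "NA"))
    need <- unname(entry$columns)
    miss <- setdiff(need[!need %in% c("insured", "is_well_visit", "stop_date")], names(dt))
    if (length(miss) > 0) stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
    present <- intersect(need, names(dt))
    dt <- dt[, present, with = FALSE]
    data.table::setnames(dt, present, names(entry$columns)[match(present, entry$columns)])
    dt
  }

  parse_dates <- function(dt, file, cols, required = cols[1]) {
    keep <- rep(TRUE, nrow(dt))
    for (col in intersect(cols, names(dt))) {
      raw <- dt[[col]]
      parsed <- as.Date(raw, format = "%Y-%m-%d")
      bad <- !is.na(raw) & is.na(parsed)
      if (col %in% required) bad <- bad | is.na(raw)
      note(file, which(bad & keep), sprintf("unparseable %s", col))
      keep <- keep & !bad
      data.table::set(dt, j = col, value = parsed)
    }
    dt[keep]
  }

  sch <- schema
  pats <- read_one(sch$patients)
  pats <- parse_dates(pats, sch$patients$file, "birth_date")
  for (col in c("smoking_ever", "mesa_resident_ever", "insured")) {
    if (col %in% names(pats)) data.table::set(pats, j = col, value = as.logical(pats[[col]]))
  }
  pid <- pats$patient_id

  dx <- read_one(sch$diagnoses)
  dx <- parse_dates(dx, sch$diagnoses$file, "date")
  if ("is_well_visit" %in% names(dx)) {
    data.table::set(dx, j = "is_well_visit", value = as.logical(dx$is_well_visit))
  } else dx[, is_well_visit := FALSE]
  note(sch$diagnoses$file, which(is.na(normalize_icd9(dx$code))), "invalid ICD-9 code")
  dx <- dx[!is.na(normalize_icd9(code))]
  note(sch$diagnoses$file, which(!dx$patient_id %in% pid), "unknown patient_id")
  dx <- dx[patient_id %in% pid]

  lb <- read_one(sch$labs)
  lb <- parse_dates(lb, sch$labs$file, "date")
  lb[, value := suppressWarnings(as.numeric(value))]
  note(sch$labs$file, which(!(is.finite(lb$value) & lb$value > 0)), "value not > 0")
  lb <- lb[is.finite(value) & value > 0]
  note(sch$labs$file, which(!lb$analyte %in% VALID_ANALYTES), "unknown analyte")
  lb <- lb[analyte %in% VALID_ANALYTES]
  note(sch$labs$file, which(!lb$patient_id %in% pid), "unknown patient_id")
  lb <- lb[patient_id %in% pid]

  md <- read_one(sch$medications)
  md <- parse_dates(md, sch$medications$file, c("start_date", "stop_date"),
                    required = "start_date")
  if (!"stop_date" %in% names(md)) md[, stop_date := as.Date(NA)]
  note(sch$medications$file, which(!md$drug_class %in% VALID_DRUG_CLASSES), "unknown drug_class")
  md <- md[drug_class %in% VALID_DRUG_CLASSES]
  note(sch$medications$file,
       which(!is.na(md$stop_date) & md$stop_date < md$start_date), "stop before start")
  md <- md[is.na(stop_date) | stop_date >= start_date]
  note(sch$medications$file, which(!md$patient_id %in% pid), "unknown patient_id")
  md <- md[patient_id %in% pid]

  en <- read_one(sch$encounters)
  en <- parse_dates(en, sch$encounters$file, "date")
  note(sch$encounters$file, which(!en$patient_id %in% pid), "unknown patient_id")
  en <- en[patient_id %in% pid]

  bm <- read_one(sch$bmi)
  bm <- parse_dates(bm, sch$bmi$file, "date")
  bm[, bmi := suppressWarnings(as.numeric(bmi))]
  note(sch$bmi$file, which(!(is.finite(bm$bmi) & bm$bmi > 0)), "bmi not > 0")
  bm <- bm[is.finite(bmi) & bmi > 0]
  note(sch$bmi$file, which(!bm$patient_id %in% pid), "unknown patient_id")
  bm <- bm[patient_id %in% pid]

  ds <- emr_dataset(pats, dx, lb, md, en, bm,
                    study_window = study_window, followup_end = followup_end)
  attr(ds, "rejected") <- if (length(rejected) > 0) do.call(rbind, rejected) else
    data.frame(file = character(), row = integer(), reason = character())
  ds
}

#' Write an EMR dataset to a directory of CSV files
#'
#' Inverse of [read_emr_dir()]: writes the six streams plus `meta.yaml`
#' (study window and follow-up end), so write-then-read round-trips.
#'
#' @param dataset An [emr_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_emr_dir <- function(dataset, dir) {
  stopifnot(inherits(dataset, "emr_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sch <- emr_schema()
  for (s in names(sch)) {
    out <- if (s == "patients") dataset$patients else dataset[[s]]
    data.table::fwrite(out, file.path(dir, sch[[s]]$file), dateTimeAs = "ISO")
  }
  yaml::write_yaml(list(study_start = as.character(dataset$study_window[1]),
                        study_end = as.character(dataset$study_window[2]),
                        followup_end = as.character(dataset$followup_end)),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}
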