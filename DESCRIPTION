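Package: t2dcohort
Title: EMR Phenotyping of Incident Type 2 Diabetes with Onset Dating and
    Matched Cohort Construction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying incident type 2 diabetes in longitudinal
    electronic medical record (EMR) extracts using a combined diagnostic-code
    and laboratory-value phenotype, assigning a clinically meaningful date of
    diabetes onset (the earlier of the first type 2 diagnostic code and the
    second abnormal glycemic laboratory result), and constructing a
    frequency-matched non-diabetic comparison cohort with randomly assigned
    reference dates. Includes engagement filtering, observation-window
    censoring at multi-year encounter gaps, covariate and outcome
    ascertainment (two-code cancer rule, modified Charlson score, visit
    frequency, medication exposure), exact binomial validation statistics,
    and a synthetic longitudinal EMR simulator with known ground-truth onset
    dates for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
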