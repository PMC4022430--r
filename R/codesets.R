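#' ICD-9 code sets with single-digit wildcards
#'
#' A code set is a named list of ICD-9 wildcard patterns in which `"X"`
#' matches exactly one digit, e.g. `"250.X0"` covers `250.00`, `250.10`,
#' ..., `250.90`. Matching ignores the dot, so `"25000"` and `"250.00"`
#' are the same code; otherwise patterns match codes of identical digit
#' length only. V and E codes are supported (`"V70.0"`, `"E849.0"`).
#'
#' @param name Short label for the set (used in messages and logs).
#' @param patterns Character vector of wildcard patterns, non-empty.
#' @return An object of class `code_set`.
#' @examples
#' t2 <- code_set("type2", c("250.X0", "250.X2"))
#' code_matches("250.10", t2)  # TRUE
#' code_matches("250.11", t2)  # FALSE
#' @export
code_set <- function(name, patterns) {
  stopifnot(is.character(name), length(name) == 1)
  if (length(patterns) == 0) stopf("code set '%s' has no patterns", name)
  bad <- patterns[!is_valid_icd9_pattern(patterns)]
  if (length(bad) > 0) {
    stopf("code set '%s': malformed ICD-9 pattern(s): %s",
          name, paste(bad, collapse = ", "))
  }
  structure(list(name = name, patterns = patterns), class = "code_set")
}

#' @export
print.code_set <- function(x, ...) {
  cat(sprintf("<code_set '%s'> %s\n", x$name, paste(x$patterns, collapse = ", ")))
  invisible(x)
}

strip_dot <- function(x) gsub(".", "", x, fixed = TRUE)

# Lexical shape of an ICD-9 code/pattern: 3-digit category (or V+2, E+3)
# plus up to two subclassification digits; when a dot is written it must
# sit right after the category. Patterns may use X in any digit slot.
icd9_shape_ok <- function(x, digit) {
  cat3 <- sprintf("(%s{3}|V%s{2}|E%s{3})", digit, digit, digit)
  dotted <- grepl(".", x, fixed = TRUE)
  ok <- logical(length(x))
  ok[dotted] <- grepl(sprintf("^%s\\.%s{1,2}$", cat3, digit), x[dotted])
  ok[!dotted] <- grepl(sprintf("^%s%s{0,2}$", cat3, digit), x[!dotted])
  ok
}

is_valid_icd9 <- function(code) icd9_shape_ok(toupper(trimws(code)), "[0-9]")

is_valid_icd9_pattern <- function(pattern) {
  icd9_shape_ok(toupper(trimws(pattern)), "[0-9X]")
}

#' Normalize an ICD-9 code to canonical dotted form
#'
#' Uppercases, strips an existing dot and re-inserts it after the category
#' part (3 digits; `Vxx`; `Exxx`) when subclassification digits follow, so
#' `"25000"` becomes `"250.00"` and `"V700"` becomes `"V70.0"`.
#'
#' @param code Character vector of ICD-9 codes.
#' @return Character vector of canonical codes; invalid entries become `NA`.
#' @export
normalize_icd9 <- function(code) {
  ok <- is_valid_icd9(code)
  raw <- strip_dot(toupper(trimws(code)))
  head_len <- ifelse(startsWith(raw, "E"), 4L, ifelse(startsWith(raw, "V"), 3L, 3L))
  out <- ifelse(nchar(raw) > head_len,
                paste0(substr(raw, 1, head_len), ".",
                       substr(raw, head_len + 1L, nchar(raw))),
                raw)
  out[!ok] <- NA_character_
  out
}

pattern_regex <- function(code_set) {
  pats <- strip_dot(toupper(code_set$patterns))
  paste0("^(", paste(gsub("X", "[0-9]", pats, fixed = TRUE), collapse = "|"), ")$")
}

#' Match ICD-9 codes against a wildcard code set
#'
#' @param code Character vector of ICD-9 codes (dotted or dotless).
#' @param code_set A [code_set()].
#' @return Logical vector, `TRUE` where the code matches any pattern.
#' @export
code_matches <- function(code, code_set) {
  if (!inherits(code_set, "code_set")) stop("code_set must be a code_set object")
  grepl(pattern_regex(code_set), strip_dot(toupper(code)))
}

#' Default ICD-9 code sets
#'
#' The shipped defaults: type 2 diabetes `250.X0/250.X2`, type 1
#' `250.X1/250.X3`, the diabetes-related exclusion set
#' (`250.X0, 250.X2, 357.2, 362.0X, 583.81`), the three cancer sites, and
#' the seven retained Charlson comorbidity categories. Every set can be
#' overridden from YAML via [read_code_sets()].
#'
#' @return Named list of `code_set` objects.
#' @export
default_code_sets <- function() {
  cs <- list(
    type2            = c("250.X0", "250.X2"),
    type1            = c("250.X1", "250.X3"),
    diabetes_related = c("250.X0", "250.X2", "357.2", "362.0X", "583.81"),
    breast_cancer    = c("174", "174.X", "175", "175.X"),
    prostate_cancer  = c("185"),
    colon_cancer     = c("153", "153.X"),
    myocardial_infarction   = c("410.XX", "410.X", "412"),
    coronary_heart_disease  = c("414.XX", "414.X", "411.XX", "411.X", "413.X"),
    peripheral_vascular     = c("443.X", "440.XX", "440.X", "441.XX", "441.X"),
    cardiovascular_disease  = c("430", "431", "432.X", "433.XX", "434.XX",
                                "435.X", "436", "437.X", "438.XX", "438.X"),
    chronic_pulmonary       = c("490", "491.XX", "491.X", "492.X", "493.XX",
                                "493.X", "494", "495.X", "496"),
    rheumatic_heart         = c("393", "394.X", "395.X", "396.X", "397.X",
                                "398.XX", "398.X"),
    renal_disease           = c("585", "585.X", "586", "582.X", "582.XX")
  )
  mapply(code_set, names(cs), cs, SIMPLIFY = FALSE)
}

#' Read code sets from a YAML file
#'
#' The file maps set names to lists of wildcard patterns, e.g.
#' ```yaml
#' type2: ["250.X0", "250.X2"]
#' ```
#' Sets absent from the file fall back to [default_code_sets()].
#'
#' @param path YAML file path.
#' @return Named list of `code_set` objects (defaults merged in).
#' @export
read_code_sets <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- default_code_sets()
  for (nm in names(raw)) {
    out[[nm]] <- code_set(nm, unlist(raw[[nm]]))
  }
  out
}
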