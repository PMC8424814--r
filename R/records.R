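# Column layouts shared by the readers, writers, generator and consolidation.

cpi_type_flags <- function() {
  c("non_drug", "change_form", "change_dose", "change_frequency",
    "change_route", "change_duration", "safety_related", "efficacy_related",
    "stop_medication", "add_medication", "drug_prescribing_step",
    "miscellaneous", "not_determined")
}

admission_risk_flags <- function() {
  c("anticholinergic", "antiarrhythmic", "dementia", "anemia",
    "heart_failure", "two_antihypertensives", "three_antihypertensives",
    "beta_blocker", "benzodiazepine", "tricyclic", "non_green_antibiotic",
    "surgical", "polypharmacy_ge8", "multi_comorbidity", "vascular",
    "acei_arb", "diuretic", "renal", "liver", "high_alert_med")
}

admission_outcomes <- function() {
  c("los_total", "los_icu_total", "losta", "losicua",
    "readmitted_30d", "died", "cost")
}

cpi_columns <- function() {
  c("patient_id", "admission_id", "cpi_order", "phase", "pharmacist_id",
    "physician_id", "accepted", cpi_type_flags(), "complexity_code",
    "intention_code", "domain_code", "consult_initiated", "outcomes_driven")
}

admission_columns <- function() {
  c("patient_id", "admission_id", "age_years", "gender", "nationality",
    "age_group", "critical", "elderly_gt84", "insured", "los_before_index",
    "los_icu_before_index", admission_risk_flags(), "n_diagnoses",
    "n_diagnoses_revised", admission_outcomes())
}

cpi_logical_columns <- function() {
  c("accepted", cpi_type_flags(), "consult_initiated", "outcomes_driven")
}

admission_logical_columns <- function() {
  c("critical", "elderly_gt84", "insured", admission_risk_flags(),
    "readmitted_30d", "died")
}

cpi_log_header <- "#cpimpact_cpi_log_v1"
consolidated_header <- "#cpimpact_consolidated_v1"

parse_flag <- function(v, column, optional = TRUE) {
  if (is.logical(v)) out <- v
  else {
    s <- tolower(trimws(as.character(v)))
    out <- rep(NA, length(s))
    out[s %in% c("true", "t", "yes", "y", "1")] <- TRUE
    out[s %in% c("false", "f", "no", "n", "0")] <- FALSE
    bad <- !is.na(s) & s != "" & s != "na" & is.na(out)
    if (any(bad)) {
      stop(sprintf("column '%s': unparseable boolean value '%s' at row %d",
                   column, s[which(bad)[1]], which(bad)[1]))
    }
  }
  if (anyNA(out)) {
    if (!optional) {
      stop(sprintf("column '%s': missing value at row %d (mandatory)",
                   column, which(is.na(out))[1]))
    }
    warning(sprintf("column '%s': %d missing value(s) defaulted to FALSE",
                    column, sum(is.na(out))), call. = FALSE)
    out[is.na(out)] <- FALSE
  }
  out
}

read_versioned_csv <- function(path, expected_header) {
  first <- readLines(path, n = 1L)
  if (!identical(first, expected_header)) {
    stop("file '", path, "' lacks the expected header line '",
         expected_header, "'")
  }
  utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE,
                  check.names = FALSE)
}

write_versioned_csv <- function(df, path, header) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = TRUE)
}

#' Read a raw CPI log
#'
#' The log emulates the study's collection tool: one row per clinical pharmacy
#' intervention (CPI), with the admission-level demographics, risk flags and
#' outcomes repeated on every row of the same admission. The first file line
#' is a version tag (`#cpimpact_cpi_log_v1`). Admission-level fields are taken
#' from the first row of each admission; disagreeing repeats are reported as
#' validation issues by [validate_dataset()], not silently averaged.
#'
#' Optional flag fields left blank default to `FALSE` with a warning;
#' mandatory fields (identifiers, acceptance, outcomes) must be present.
#'
#' @param path Path to a `cpi_log.csv` written by [write_cpi_log()] or
#'   following the same layout.
#' @return A list with data frames `cpi` (one row per CPI) and `admissions`
#'   (one row per admission).
#' @export
read_cpi_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read_versioned_csv(path, cpi_log_header)
  needed <- unique(c(cpi_columns(), admission_columns()))
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("cpi log is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    return(list(cpi = empty_cpi_table(), admissions = empty_admission_table()))
  }
  for (cl in cpi_logical_columns()) {
    raw[[cl]] <- parse_flag(raw[[cl]], cl, optional = cl != "accepted")
  }
  for (cl in admission_logical_columns()) {
    optional <- !(cl %in% c("readmitted_30d", "died"))
    raw[[cl]] <- parse_flag(raw[[cl]], cl, optional = optional)
  }
  bad_cc <- !raw$complexity_code %in% c(0, 0.5, 1)
  if (any(bad_cc)) {
    stop(sprintf("column 'complexity_code': invalid value '%s' at row %d",
                 raw$complexity_code[which(bad_cc)[1]], which(bad_cc)[1]))
  }
  bad_ph <- !raw$phase %in% c("I", "II")
  if (any(bad_ph)) {
    stop(sprintf("column 'phase': invalid value '%s' at row %d",
                 raw$phase[which(bad_ph)[1]], which(bad_ph)[1]))
  }
  cpi <- raw[, cpi_columns()]
  first <- !duplicated(raw$admission_id)
  admissions <- raw[first, admission_columns()]
  rownames(cpi) <- rownames(admissions) <- NULL
  list(cpi = cpi, admissions = admissions)
}

#' Write a raw CPI log
#'
#' Inverse of [read_cpi_log()]: joins the admission-level fields onto every
#' CPI row and writes a versioned CSV. Numeric fields round-trip to at least
#' 12 significant digits.
#'
#' @param cpi,admissions Tables as returned by [read_cpi_log()] or
#'   [generate_cpi_data()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cpi_log <- function(cpi, admissions, path) {
  adm_extra <- admissions[, setdiff(admission_columns(),
                                    c("patient_id", "admission_id"))]
  idx <- match(cpi$admission_id, admissions$admission_id)
  if (anyNA(idx)) {
    stop("cpi rows reference admission_id absent from the admission table: ",
         paste(unique(cpi$admission_id[is.na(idx)]), collapse = ", "))
  }
  out <- cbind(cpi, adm_extra[idx, , drop = FALSE])
  write_versioned_csv(out, path, cpi_log_header)
  invisible(path)
}

empty_cpi_table <- function() {
  out <- data.frame(matrix(nrow = 0, ncol = length(cpi_columns())))
  names(out) <- cpi_columns()
  out
}

empty_admission_table <- function() {
  out <- data.frame(matrix(nrow = 0, ncol = length(admission_columns())))
  names(out) <- admission_columns()
  out
}

issue <- function(severity, key, message) {
  data.frame(severity = severity, key = key, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a CPI dataset
#'
#' A total reporting operation: it never throws on bad data, it describes it.
#' Checks referential integrity (every CPI points at an admission), uniqueness
#' of the CPI order index within an admission, the length-of-stay ordering
#' invariants (post-index stay cannot exceed total stay, ICU stay cannot
#' exceed hospital stay), the derived-flag definitions (elderly means
#' age > 84), non-negative durations and costs, and enum domains.
#'
#' @param cpi,admissions Tables as returned by [read_cpi_log()].
#' @return A data frame of issues with columns `severity` (`"error"` or
#'   `"warning"`), `key` (record identifier) and `message`; zero rows when the
#'   dataset is clean.
#' @export
validate_dataset <- function(cpi, admissions) {
  issues <- list()
  add <- function(x) issues[[length(issues) + 1L]] <<- x

  unknown <- !cpi$admission_id %in% admissions$admission_id
  for (i in which(unknown)) {
    add(issue("error", paste0(cpi$admission_id[i], "#", cpi$cpi_order[i]),
              "CPI references an admission_id absent from the admission table"))
  }
  dup <- duplicated(cpi[, c("admission_id", "cpi_order")])
  for (i in which(dup)) {
    add(issue("error", paste0(cpi$admission_id[i], "#", cpi$cpi_order[i]),
              "duplicate cpi_order within admission"))
  }
  bad_cc <- !cpi$complexity_code %in% c(0, 0.5, 1)
  for (i in which(bad_cc)) {
    add(issue("error", paste0(cpi$admission_id[i], "#", cpi$cpi_order[i]),
              sprintf("complexity_code %s not in {0, 0.5, 1}",
                      cpi$complexity_code[i])))
  }
  a <- admissions
  chk <- function(bad, msg) {
    for (i in which(bad)) add(issue("error", a$admission_id[i], msg))
  }
  chk(a$losta > a$los_total + 1e-9,
      "post-index stay (losta) exceeds total stay (los_total)")
  chk(a$los_icu_total > a$los_total + 1e-9,
      "ICU stay (los_icu_total) exceeds total stay (los_total)")
  chk(a$losicua > a$los_icu_total + 1e-9,
      "post-index ICU stay (losicua) exceeds total ICU stay (los_icu_total)")
  chk(a$elderly_gt84 != (a$age_years > 84),
      "elderly_gt84 flag inconsistent with age_years")
  chk(a$age_years < 0, "negative age")
  chk(a$los_before_index < 0 | a$los_icu_before_index < 0 |
        a$losta < 0 | a$losicua < 0 | a$los_total < 0 | a$los_icu_total < 0,
      "negative length of stay")
  chk(a$cost < 0, "negative cost")
  chk(a$n_diagnoses_revised > a$n_diagnoses,
      "more revised diagnoses than diagnoses")
  chk(duplicated(a$admission_id), "duplicate admission_id")
  no_cpi <- !a$admission_id %in% cpi$admission_id
  for (i in which(no_cpi)) {
    add(issue("warning", a$admission_id[i], "admission has no CPI rows"))
  }
  if (length(issues) == 0L) {
    return(issue("error", "x", "y")[0, ])
  }
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}
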