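#' Study-period provider success/rejection rates
#'
#' A pharmacist's success rate is the number of physician-authorized CPI
#' divided by the total CPI that pharmacist recommended over the whole
#' dataset; a physician's rejection rate is the fraction of CPI addressed to
#' that physician that were rejected. Providers with no CPI are absent from
#' the result.
#'
#' @param cpi A CPI table (one row per intervention).
#' @return An object of class `provider_rates`: list with named numeric
#'   vectors `pharmacist_success` and `physician_rejection`.
#' @export
#' @examples
#' cpi <- data.frame(pharmacist_id = c("a", "a", "b"),
#'                   physician_id = c("x", "y", "x"),
#'                   accepted = c(TRUE, FALSE, TRUE))
#' compute_provider_rates(cpi)$pharmacist_success  # a = 0.5, b = 1
compute_provider_rates <- function(cpi) {
  if (nrow(cpi) == 0L) stop("cannot compute provider rates from an empty CPI table")
  ph <- tapply(cpi$accepted, cpi$pharmacist_id, mean)
  md <- tapply(!cpi$accepted, cpi$physician_id, mean)
  structure(list(pharmacist_success = c(ph), physician_rejection = c(md)),
            class = "provider_rates")
}

# Scores computed over one admission's CPI. `descriptive_cpi` selects the CPI
# used for the six scores describing the recommendations themselves
# (complexity, intention, domain, prescribing step, consultancy, outcomes
# driven); `all_cpi` always drives the rejection fraction and the two
# provider-history scores under the default "mixed"/"admission" scopes.
score_set <- function(descriptive_cpi, all_cpi, rates, admission,
                      rejection_cpi = all_cpi) {
  stopifnot(nrow(descriptive_cpi) > 0L, nrow(all_cpi) > 0L)
  miss_ph <- setdiff(all_cpi$pharmacist_id, names(rates$pharmacist_success))
  if (length(miss_ph) > 0L) {
    stop("pharmacist(s) missing from provider rates: ",
         paste(miss_ph, collapse = ", "))
  }
  miss_md <- setdiff(all_cpi$physician_id, names(rates$physician_rejection))
  if (length(miss_md) > 0L) {
    stop("physician(s) missing from provider rates: ",
         paste(miss_md, collapse = ", "))
  }
  d <- descriptive_cpi
  data.frame(
    problem_complexity = mean(d$complexity_code),
    problem_intention = mean(d$intention_code),
    clinical_domain = mean(d$domain_code),
    prescribing_step = mean(d$drug_prescribing_step),
    consultancy = mean(d$consult_initiated),
    outcomes_driven = mean(d$outcomes_driven),
    rejection = mean(!rejection_cpi$accepted),
    combined_cp_success =
      mean(rates$pharmacist_success[all_cpi$pharmacist_id]),
    physician_rejection =
      mean(rates$physician_rejection[all_cpi$physician_id]),
    diagnosis_revision =
      if (admission$n_diagnoses > 0) {
        admission$n_diagnoses_revised / admission$n_diagnoses
      } else 0
  )
}

#' Consolidation scores for one admission
#'
#' Computes the ten ordinal scores (all in \[0, 1\]) that summarize an
#' admission's CPI: means of the per-CPI complexity/intention/domain codes,
#' fractions of prescribing-step, consult-initiated and outcomes-driven CPI,
#' the fraction of CPI rejected in the admission, the mean study-period
#' success rate of the intervening pharmacists and rejection rate of the
#' ordering physicians, and the fraction of the admission's diagnoses that
#' were revised.
#'
#' @param cpi CPI rows of a single admission.
#' @param rates A `provider_rates` object covering every provider in `cpi`.
#' @param admission The admission's row (for the diagnosis-revision score).
#' @return A one-row data frame with the ten score columns.
#' @export
compute_scores <- function(cpi, rates, admission) {
  if (nrow(cpi) == 0L) stop("cannot score an admission with no CPI")
  if (length(unique(cpi$admission_id)) != 1L) {
    stop("compute_scores expects the CPI of exactly one admission")
  }
  score_set(cpi, cpi, rates, admission)
}

#' Consolidate one admission's CPI
#'
#' Collapses the admission's CPI into at most one "accepted" and one
#' "rejected" summary record. Recommendation-type flags aggregate by logical
#' OR over the status subgroup's CPI; the admission's demographics, risk flags
#' and outcomes are copied onto both records; `total_cpi` counts all CPI of
#' the admission; `phase` is the phase of the earliest CPI.
#'
#' Score scope (`score_scope`):
#' \describe{
#'   \item{`"mixed"` (default)}{the six scores describing the recommendations
#'     (complexity, intention, domain, prescribing step, consultancy,
#'     outcomes driven) are computed over the status subgroup's own CPI;
#'     the rejection fraction and the provider-history scores over all CPI of
#'     the admission.}
#'   \item{`"admission"`}{all scores over all CPI of the admission.}
#'   \item{`"subgroup"`}{all scores, including the rejection fraction, over
#'     the subgroup (so an accepted record always has rejection 0 and a
#'     rejected record 1); provider-history and diagnosis-revision scores are
#'     admission/study-period quantities by definition and stay so.}
#' }
#'
#' @param cpi CPI rows of a single admission.
#' @param admission The admission's row.
#' @param rates A `provider_rates` object.
#' @param score_scope See above.
#' @return A data frame with one or two rows (statuses present in the
#'   admission).
#' @export
consolidate_admission <- function(cpi, admission, rates,
                                  score_scope = c("mixed", "admission",
                                                  "subgroup")) {
  score_scope <- match.arg(score_scope)
  if (nrow(cpi) == 0L) stop("cannot consolidate an admission with no CPI")
  phase <- cpi$phase[order(cpi$cpi_order)][1]
  statuses <- unique(ifelse(cpi$accepted, "accepted", "rejected"))
  statuses <- intersect(c("accepted", "rejected"), statuses)
  rows <- lapply(statuses, function(st) {
    sub <- cpi[(cpi$accepted) == (st == "accepted"), , drop = FALSE]
    sc <- switch(score_scope,
      mixed = score_set(sub, cpi, rates, admission),
      admission = score_set(cpi, cpi, rates, admission),
      subgroup = score_set(sub, cpi, rates, admission, rejection_cpi = sub))
    flags <- as.data.frame(lapply(cpi_type_flags(),
                                  function(f) any(sub[[f]])))
    names(flags) <- cpi_type_flags()
    adm_fields <- admission[, setdiff(admission_columns(),
                                      c("patient_id", "admission_id"))]
    cbind(
      data.frame(patient_id = admission$patient_id,
                 admission_id = admission$admission_id,
                 status = st, total_cpi = nrow(cpi), phase = phase,
                 stringsAsFactors = FALSE),
      adm_fields, flags, sc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Consolidate a full CPI dataset
#'
#' Two-pass design: provider rates are computed over the whole dataset first
#' (they are study-period quantities), then each admission is collapsed with
#' [consolidate_admission()]. The output has one row per non-empty
#' (admission, status) subgroup. Re-consolidating an already consolidated
#' table is rejected.
#'
#' @param cpi,admissions Tables as returned by [read_cpi_log()] or
#'   [generate_cpi_data()].
#' @inheritParams consolidate_admission
#' @return A data frame of consolidated records with class
#'   `cpi_consolidated`.
#' @export
consolidate_dataset <- function(cpi, admissions,
                                score_scope = c("mixed", "admission",
                                                "subgroup")) {
  score_scope <- match.arg(score_scope)
  if (inherits(cpi, "cpi_consolidated")) {
    stop("input is already consolidated; refusing to aggregate twice")
  }
  if (nrow(cpi) == 0L) {
    out <- empty_consolidated_table()
    class(out) <- c("cpi_consolidated", class(out))
    return(out)
  }
  rates <- compute_provider_rates(cpi)
  idx <- split(seq_len(nrow(cpi)), cpi$admission_id)
  adm_lookup <- match(names(idx), admissions$admission_id)
  if (anyNA(adm_lookup)) {
    stop("CPI reference admissions absent from the admission table: ",
         paste(names(idx)[is.na(adm_lookup)], collapse = ", "))
  }
  pieces <- lapply(seq_along(idx), function(i) {
    consolidate_admission(cpi[idx[[i]], , drop = FALSE],
                          admissions[adm_lookup[i], , drop = FALSE],
                          rates, score_scope)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$admission_id, out$status), ]
  rownames(out) <- NULL
  class(out) <- c("cpi_consolidated", class(out))
  out
}

consolidated_columns <- function() {
  c("patient_id", "admission_id", "status", "total_cpi", "phase",
    setdiff(admission_columns(), c("patient_id", "admission_id")),
    cpi_type_flags(),
    c("problem_complexity", "problem_intention", "clinical_domain",
      "prescribing_step", "consultancy", "outcomes_driven", "rejection",
      "combined_cp_success", "physician_rejection", "diagnosis_revision"))
}

empty_consolidated_table <- function() {
  out <- data.frame(matrix(nrow = 0, ncol = length(consolidated_columns())))
  names(out) <- consolidated_columns()
  out
}

#' Read/write consolidated record tables
#'
#' Versioned CSV (`#cpimpact_consolidated_v1`) holding one row per
#' consolidated record.
#'
#' @param records A `cpi_consolidated` table.
#' @param path File path.
#' @return `read_consolidated()` returns the table with class
#'   `cpi_consolidated`; `write_consolidated()` returns `path` invisibly.
#' @export
write_consolidated <- function(records, path) {
  write_versioned_csv(as.data.frame(records), path, consolidated_header)
  invisible(path)
}

#' @rdname write_consolidated
#' @export
read_consolidated <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- read_versioned_csv(path, consolidated_header)
  missing_cols <- setdiff(consolidated_columns(), names(out))
  if (length(missing_cols) > 0L) {
    stop("consolidated table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (cl in c(cpi_type_flags(), admission_logical_columns())) {
    out[[cl]] <- parse_flag(out[[cl]], cl)
  }
  class(out) <- c("cpi_consolidated", class(out))
  out
}
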