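#' Model input schema for consolidated CPI records
#'
#' The predictive model takes 54 inputs per consolidated record: 36 variables
#' whose distributions were comparable between accepted and rejected records
#' ("matched": demographics, hospitalization-risk flags, recommendation-type
#' flags, and six consolidation scores) and 18 that differed ("unmatched":
#' study phase, CPI count, further risk flags and recommendation types, and
#' four provider/rejection scores). An optional extra binary input carries the
#' accepted/rejected status of the record itself.
#'
#' Each schema row maps one model input to a column of a consolidated record
#' table: `name` is the feature name, `source` the record column, `kind` is
#' `"continuous"` or `"binary"`, `level` the factor level coded as 1 for
#' binary features derived from character columns (NA for logical columns),
#' and `group` the variable group label used when related columns must be
#' permuted or reported together (two-level categoricals encode to a single
#' column, so groups are singletons under the default schema).
#'
#' @param variables Which block of inputs to include: `"all"` (54),
#'   `"matched"` (36) or `"unmatched"` (18).
#' @param include_status Add the accepted/rejected status indicator
#'   (1 = accepted) as an extra binary input.
#' @return A data frame with columns `name`, `source`, `kind`, `level`,
#'   `group` and one row per model input column.
#' @export
#' @examples
#' nrow(cpi_feature_schema())                        # 54
#' nrow(cpi_feature_schema(include_status = TRUE))   # 55
cpi_feature_schema <- function(variables = c("all", "matched", "unmatched"),
                               include_status = FALSE) {
  variables <- match.arg(variables)
  con <- function(name, source = name) {
    data.frame(name = name, source = source, kind = "continuous",
               level = NA_character_, group = name, stringsAsFactors = FALSE)
  }
  bin <- function(name, source = name, level = NA_character_) {
    data.frame(name = name, source = source, kind = "binary",
               level = level, group = name, stringsAsFactors = FALSE)
  }
  matched <- rbind(
    con("age_years"),
    bin("gender_male", "gender", "M"),
    bin("nationality_jordanian", "nationality", "Jordanian"),
    bin("age_group_adult", "age_group", "adult"),
    bin("critical"),
    bin("elderly_gt84"),
    bin("insured"),
    con("los_before_index"),
    con("los_icu_before_index"),
    do.call(rbind, lapply(c(
      "anticholinergic", "antiarrhythmic", "dementia", "anemia",
      "heart_failure", "two_antihypertensives", "three_antihypertensives",
      "beta_blocker", "benzodiazepine", "tricyclic", "non_green_antibiotic",
      "surgical"), bin)),
    do.call(rbind, lapply(c(
      "non_drug", "change_form", "change_dose", "change_frequency",
      "change_route", "change_duration", "safety_related", "miscellaneous",
      "not_determined"), bin)),
    do.call(rbind, lapply(c(
      "problem_complexity", "problem_intention", "clinical_domain",
      "prescribing_step", "outcomes_driven", "diagnosis_revision"), con))
  )
  unmatched <- rbind(
    bin("phase_ii", "phase", "II"),
    con("total_cpi"),
    do.call(rbind, lapply(c(
      "polypharmacy_ge8", "multi_comorbidity", "vascular", "acei_arb",
      "diuretic", "renal", "liver", "high_alert_med"), bin)),
    do.call(rbind, lapply(c(
      "drug_prescribing_step", "efficacy_related", "stop_medication",
      "add_medication"), bin)),
    do.call(rbind, lapply(c(
      "consultancy", "rejection", "combined_cp_success",
      "physician_rejection"), con))
  )
  schema <- switch(variables,
                   all = rbind(matched, unmatched),
                   matched = matched,
                   unmatched = unmatched)
  if (include_status) {
    schema <- rbind(schema, bin("status_accepted", "status", "accepted"))
  }
  rownames(schema) <- NULL
  schema
}

#' Encode consolidated records as a numeric feature matrix
#'
#' Continuous columns are centered and scaled (parameters estimated from the
#' supplied rows when `scaling` is `NULL`, i.e. on the training set, and frozen
#' thereafter); logical and two-level categorical columns become 0/1.
#' Zero-spread columns keep a unit spread so constant inputs encode to a
#' constant column instead of NaN.
#'
#' @param records A consolidated record table (see [consolidate_dataset()]).
#' @param schema A schema from [cpi_feature_schema()].
#' @param scaling `NULL` to fit scaling on `records`, or the `scaling` element
#'   of a previously built feature set to reuse frozen parameters.
#' @param method `"zscore"` (center = mean, spread = sd) or `"minmax"`
#'   (center = min, spread = range). Ignored when `scaling` is supplied.
#' @return An object of class `cpi_features`: list with the numeric matrix
#'   `x` (rownames = `<admission_id>:<status>`), the `schema`, and the frozen
#'   `scaling` (data frame of column, center, spread).
#' @export
encode_features <- function(records, schema, scaling = NULL,
                            method = c("zscore", "minmax")) {
  method <- match.arg(method)
  if (nrow(records) == 0L) stop("cannot encode an empty record set")
  missing_cols <- setdiff(schema$source, names(records))
  if (length(missing_cols) > 0L) {
    stop("records lack columns required by the schema: ",
         paste(missing_cols, collapse = ", "))
  }
  x <- matrix(NA_real_, nrow = nrow(records), ncol = nrow(schema),
              dimnames = list(paste(records$admission_id, records$status,
                                    sep = ":"),
                              schema$name))
  for (j in seq_len(nrow(schema))) {
    src <- records[[schema$source[j]]]
    if (schema$kind[j] == "binary") {
      if (is.logical(src)) {
        x[, j] <- as.numeric(src)
      } else {
        lev <- schema$level[j]
        if (is.na(lev)) src <- as.logical(src) else src <- src == lev
        x[, j] <- as.numeric(src)
      }
    } else {
      x[, j] <- as.numeric(src)
    }
  }
  if (anyNA(x)) {
    bad <- colnames(x)[colSums(is.na(x)) > 0]
    stop("missing values after encoding in: ", paste(bad, collapse = ", "))
  }
  cont <- schema$name[schema$kind == "continuous"]
  if (is.null(scaling)) {
    center <- spread <- numeric(length(cont))
    for (k in seq_along(cont)) {
      v <- x[, cont[k]]
      if (method == "zscore") {
        center[k] <- mean(v)
        spread[k] <- stats::sd(v)
      } else {
        center[k] <- min(v)
        spread[k] <- max(v) - min(v)
      }
      if (!is.finite(spread[k]) || spread[k] == 0) spread[k] <- 1
    }
    scaling <- data.frame(column = cont, center = center, spread = spread,
                          stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(scaling))) {
    cl <- scaling$column[k]
    if (cl %in% colnames(x)) {
      x[, cl] <- (x[, cl] - scaling$center[k]) / scaling$spread[k]
    }
  }
  structure(list(x = x, schema = schema, scaling = scaling),
            class = "cpi_features")
}
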