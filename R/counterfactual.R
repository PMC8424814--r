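outcome_task <- function(outcome) {
  tasks <- c(losta = "continuous", losicua = "continuous",
             cost = "continuous", los_total = "continuous",
             readmitted_30d = "categorical", died = "categorical")
  if (!outcome %in% names(tasks)) {
    stop("unknown outcome '", outcome, "'; expected one of ",
         paste(names(tasks), collapse = ", "))
  }
  tasks[[outcome]]
}

#' Fit an outcome model on consolidated records
#'
#' Convenience wrapper tying the feature encoder to [grnn_fit()]: encodes the
#' training records under `schema` (fitting the continuous-column scaling on
#' these rows, frozen thereafter), and trains a GRNN for the chosen outcome.
#' The default schema uses the 18 unmatched variables plus the CPI status
#' indicator (19 inputs).
#'
#' @param records Consolidated training records.
#' @param outcome One of `losta`, `losicua`, `cost` (continuous) or
#'   `readmitted_30d`, `died` (categorical).
#' @param schema Feature schema, see [cpi_feature_schema()].
#' @param stop Stop conditions for bandwidth training.
#' @param scaling_method Passed to [encode_features()].
#' @param per_feature Select one bandwidth per input (automatic relevance;
#'   see [grnn_fit()]). Recommended for counterfactual reassignment.
#' @return An object of class `cpi_outcome_model` wrapping the `grnn`.
#' @export
fit_outcome_model <- function(records, outcome = "losta",
                              schema = cpi_feature_schema("unmatched",
                                                          include_status = TRUE),
                              stop = grnn_stop_conditions(),
                              scaling_method = "zscore",
                              per_feature = FALSE) {
  task <- outcome_task(outcome)
  feats <- encode_features(records, schema, method = scaling_method)
  y <- records[[outcome]]
  # bandwidths are validated leave-one-admission-out: the accepted and
  # rejected records of one admission share its outcomes, and ungrouped
  # leave-one-out would reward bandwidths that just re-find the twin record
  model <- grnn_fit(feats, y, task = task, stop = stop,
                    per_feature = per_feature,
                    groups = records$admission_id)
  structure(list(grnn = model, outcome = outcome, task = task,
                 schema = schema, scaling = feats$scaling,
                 scaling_method = scaling_method),
            class = "cpi_outcome_model")
}

#' @export
predict.cpi_outcome_model <- function(object, newdata, ...) {
  feats <- encode_features(newdata, object$schema, scaling = object$scaling)
  predict.grnn(object$grnn, feats, ...)
}

#' Reassignment policy: mark every CPI accepted
#'
#' The default policy edits only the record's own status and its admission
#' rejection fraction (status → accepted, rejection → 0). The extended policy
#' additionally resets the provider-history scores (combined CP success → 1,
#' physician rejection → 0), treating the providers as if they had never had
#' rejections. Both are idempotent.
#'
#' @param type `"default"`, `"extended"`, or `"none"` (empty edit set).
#' @return An object of class `reassignment_policy` (named list of edits).
#' @export
reassignment_policy <- function(type = c("default", "extended", "none")) {
  type <- match.arg(type)
  edits <- switch(type,
    none = list(),
    default = list(status = "accepted", rejection = 0),
    extended = list(status = "accepted", rejection = 0,
                    combined_cp_success = 1, physician_rejection = 0))
  structure(edits, class = "reassignment_policy", policy_type = type)
}

#' Apply a reassignment policy to consolidated records
#'
#' Pure function: returns an edited copy, the input is untouched; fields not
#' named by the policy are preserved exactly.
#'
#' @param records Consolidated records.
#' @param policy A [reassignment_policy()] (or a plain named list of edits).
#' @return The edited records.
#' @export
reassign <- function(records, policy = reassignment_policy()) {
  unknown <- setdiff(names(policy), names(records))
  if (length(unknown) > 0L) {
    stop("policy edits unknown field(s): ", paste(unknown, collapse = ", "))
  }
  out <- records
  for (f in names(policy)) out[[f]] <- policy[[f]]
  out
}

#' Paired comparison of factual vs all-accepted scenarios
#'
#' Predicts the outcome for every consolidated record under its observed
#' inputs (factual scenario, ~80% acceptance) and under the reassignment
#' policy (counterfactual, 100% acceptance), then compares the paired
#' predictions: a Wilcoxon signed-rank test for continuous outcomes, a
#' continuity-corrected McNemar test on the discordant predicted classes for
#' categorical ones. Records that served as training exemplars are predicted
#' exactly like any other query.
#'
#' @param model A `cpi_outcome_model`.
#' @param records Consolidated records to reassign.
#' @param policy A [reassignment_policy()].
#' @return An object of class `cpi_counterfactual`: per-record predictions,
#'   scenario summaries in `mean ± sd` / `median (range)` form, the paired
#'   test, and for continuous outcomes two effect summaries:
#'   `mean_difference`, the mean per-record scenario difference (factual −
#'   counterfactual) over all records (for the cost outcome this is the mean
#'   saving in JD per consolidated record), and `mean_difference_edited`, the
#'   same mean restricted to records whose inputs the policy actually changed.
#'   The overall mean dilutes the effect across the untouched
#'   fully-accepted admissions, so the edited-record mean is the estimate of
#'   the outcome change per record of an admission with rejections.
#' @export
run_counterfactual <- function(model, records,
                               policy = reassignment_policy()) {
  if (!inherits(model, "cpi_outcome_model")) {
    stop("model must be a cpi_outcome_model")
  }
  cf_records <- reassign(records, policy)
  key <- paste(records$admission_id, records$status, sep = ":")
  edited <- rep(FALSE, nrow(records))
  for (f in names(policy)) {
    edited <- edited | records[[f]] != policy[[f]]
  }
  if (model$task == "continuous") {
    factual <- predict(model, records)
    counterfactual <- predict(model, cf_records)
    diff <- factual - counterfactual
    test <- paired_continuous_test(diff)
    summ <- data.frame(
      scenario = c("factual_80pct", "counterfactual_100pct"),
      mean_sd = c(fmt_mean_sd(factual), fmt_mean_sd(counterfactual)),
      median_range = c(fmt_median_range(factual),
                       fmt_median_range(counterfactual)),
      stringsAsFactors = FALSE)
    out <- list(outcome = model$outcome, task = model$task,
                predictions = data.frame(key = key, factual = factual,
                                         counterfactual = counterfactual,
                                         stringsAsFactors = FALSE),
                summary = summ,
                mean_difference = mean(diff),
                mean_difference_edited =
                  if (any(edited)) mean(diff[edited]) else NA_real_,
                n_edited = sum(edited),
                test = test)
  } else {
    factual <- predict(model, records)
    counterfactual <- predict(model, cf_records)
    pos <- model$grnn$class_levels[length(model$grnn$class_levels)]
    b <- sum(factual != pos & counterfactual == pos)
    cc <- sum(factual == pos & counterfactual != pos)
    test <- paired_categorical_test(b, cc)
    summ <- data.frame(
      scenario = c("factual_80pct", "counterfactual_100pct"),
      positive = c(sprintf("%s: %d (%.1f%%)", pos, sum(factual == pos),
                           100 * mean(factual == pos)),
                   sprintf("%s: %d (%.1f%%)", pos, sum(counterfactual == pos),
                           100 * mean(counterfactual == pos))),
      stringsAsFactors = FALSE)
    out <- list(outcome = model$outcome, task = model$task,
                predictions = data.frame(key = key, factual = factual,
                                         counterfactual = counterfactual,
                                         stringsAsFactors = FALSE),
                summary = summ,
                discordant = c(to_positive = b, to_negative = cc),
                test = test)
  }
  structure(out, class = "cpi_counterfactual")
}

#' @export
print.cpi_counterfactual <- function(x, ...) {
  cat("Counterfactual reassignment analysis —", x$outcome, "\n")
  print(x$summary, row.names = FALSE)
  if (x$task == "continuous") {
    cat(sprintf("mean scenario difference (factual - counterfactual): %.3f\n",
                x$mean_difference))
    cat(sprintf("mean difference over the %d policy-edited records: %.3f\n",
                x$n_edited, x$mean_difference_edited))
  } else {
    cat(sprintf("discordant predictions: %d and %d\n",
                x$discordant[["to_positive"]], x$discordant[["to_negative"]]))
  }
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n",
              x$test$method, x$test$statistic, x$test$p_value))
  invisible(x)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped (Wilcoxon's rule); if none remain the test is
#' degenerate and p = 1 by convention. The exact distribution is used for up
#' to 25 untied nonzero differences, the tie-corrected normal approximation
#' with continuity correction otherwise.
#'
#' @param differences Numeric vector of paired differences.
#' @return A list with `method`, `statistic` (V), `p_value`, `n` (nonzero
#'   pairs used).
#' @export
paired_continuous_test <- function(differences) {
  if (length(differences) < 1L) stop("need at least one difference")
  d <- differences[differences != 0]
  if (length(d) == 0L) {
    return(list(method = "Wilcoxon signed-rank", statistic = 0,
                p_value = 1, n = 0L))
  }
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  res <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = TRUE))
  list(method = "Wilcoxon signed-rank",
       statistic = unname(res$statistic), p_value = res$p.value,
       n = length(d))
}

#' Continuity-corrected McNemar test
#'
#' For paired binary outcomes with discordant counts `b` (switching to the
#' positive class) and `c` (switching away): chi-squared statistic
#' `(max(|b - c| - 1, 0))^2 / (b + c)` on 1 df. The correction is clamped at
#' zero so perfect symmetry (b = c) gives statistic 0; no discordant pairs
#' give p = 1.
#'
#' @param b,c Non-negative discordant counts.
#' @return A list with `method`, `statistic`, `p_value`, `b`, `c`.
#' @export
paired_categorical_test <- function(b, c) {
  if (b < 0 || c < 0) stop("discordant counts must be non-negative")
  if (b + c == 0) {
    return(list(method = "McNemar (continuity-corrected)", statistic = 0,
                p_value = 1, b = b, c = c))
  }
  stat <- max(abs(b - c) - 1, 0)^2 / (b + c)
  list(method = "McNemar (continuity-corrected)", statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       b = b, c = c)
}
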