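#' Mann-Whitney U test for two unpaired samples
#'
#' Two-sided; the exact distribution is used when the smaller sample has at
#' most 8 observations and there are no ties, the tie-corrected normal
#' approximation with continuity correction otherwise.
#'
#' @param a,b Numeric samples.
#' @return A list with `method`, `statistic` (U), `p_value`, `n`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(method = "Mann-Whitney U", statistic = unname(res$statistic),
       p_value = res$p.value, n = c(length(a), length(b)))
}

#' Pearson chi-squared test on a 2 x k count table
#'
#' No continuity correction; degrees of freedom k - 1.
#'
#' @param counts A 2-row matrix of non-negative counts.
#' @return A list with `method`, `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_squared(matrix(c(80, 439, 40, 125), nrow = 2, byrow = TRUE))
chi_squared <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L) stop("expected a 2 x k table")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("table has a zero marginal")
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(method = "Pearson chi-squared", statistic = unname(res$statistic),
       df = unname(res$parameter), p_value = res$p.value)
}

#' Sample size for a paired mean change
#'
#' Number of pairs needed to detect a mean paired difference `effect` with
#' standard deviation of change `sd_change` at two-tailed level `alpha` and
#' the given power. The z form is
#' `ceil(((z_{1-alpha/2} + z_{power}) * sd / effect)^2)`; the t form iterates
#' the same expression with t quantiles at n - 1 degrees of freedom, starting
#' from the z solution, until self-consistent. Results always round up.
#'
#' With alpha 0.05, power 0.80, sd 1.05 days and effect 0.125 days (a
#' three-hour change in stay) this gives 554 pairs with the z approximation
#' and 556 with the t statistic.
#'
#' @param alpha Two-tailed type-I error.
#' @param power Desired power (1 - beta).
#' @param sd_change Standard deviation of the paired differences.
#' @param effect Smallest mean difference worth detecting (same units).
#' @param statistic `"z"` or `"t"`.
#' @return The required number of pairs (integer).
#' @export
paired_mean_change_n <- function(alpha = 0.05, power = 0.80, sd_change = 1.05,
                                 effect = 0.125, statistic = c("z", "t")) {
  statistic <- match.arg(statistic)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  if (sd_change <= 0) stop("sd_change must be positive")
  if (effect <= 0) stop("effect must be positive")
  n_z <- ceiling(((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) *
                    sd_change / effect)^2)
  if (statistic == "z") return(as.integer(n_z))
  n <- max(2, n_z)
  repeat {
    n_new <- ceiling(((stats::qt(1 - alpha / 2, n - 1) +
                         stats::qt(power, n - 1)) * sd_change / effect)^2)
    if (n_new == n) break
    n <- n_new
  }
  as.integer(n)
}

#' Exemplar-network sample-size heuristic
#'
#' The rule-of-thumb minimum training size for the two-summation-node
#' exemplar network: number of input variables times 10 times the number of
#' second-layer neurons (2). 19 inputs give 380; 54 give 1080.
#'
#' @param n_inputs Number of input variables.
#' @param n_second_layer Neurons in the summation layer (default 2).
#' @return The heuristic sample size (integer).
#' @export
ann_sample_heuristic <- function(n_inputs, n_second_layer = 2) {
  if (n_inputs < 1 || n_second_layer < 1) {
    stop("n_inputs and n_second_layer must be positive")
  }
  as.integer(n_inputs * 10 * n_second_layer)
}

#' Univariate accepted-vs-rejected comparisons
#'
#' For every model input (plus, optionally, the outcomes): continuous
#' variables are compared between the accepted and rejected consolidated
#' records with [mann_whitney_u()], binary ones with [chi_squared()] on the
#' 2 x 2 count table. Summaries use the registry display conventions
#' (`median (min–max)` and `Yes: n (p%)`). P-values of 0.10 or larger are
#' blanked in the display column (as in the published tables) but kept in
#' `p_value`; variables that are constant overall, or whose 2 x 2 table has a
#' zero marginal, get `NA`. No multiple-testing correction is applied (a
#' caveat worth keeping in mind when reading the table).
#'
#' @param records A consolidated record table containing both statuses.
#' @param schema Which variables to compare (default: all 54 model inputs).
#' @param include_outcomes Also compare the outcome columns.
#' @return A data frame with one row per variable: `variable`, `type`,
#'   `accepted`, `rejected` (formatted summaries), `statistic`, `p_value`,
#'   `p_display`.
#' @export
compare_groups <- function(records, schema = cpi_feature_schema("all"),
                           include_outcomes = FALSE) {
  acc <- records[records$status == "accepted", , drop = FALSE]
  rej <- records[records$status == "rejected", , drop = FALSE]
  if (nrow(acc) == 0L || nrow(rej) == 0L) {
    stop("both accepted and rejected records are required")
  }
  feats <- encode_features(records, schema,
                           scaling = data.frame(column = character(0),
                                                center = numeric(0),
                                                spread = numeric(0)))
  x <- feats$x
  is_acc <- records$status == "accepted"
  rows <- lapply(seq_len(nrow(schema)), function(j) {
    v <- x[, j]
    kind <- schema$kind[j]
    if (kind == "continuous") {
      summ_a <- fmt_median_range(v[is_acc], 2)
      summ_r <- fmt_median_range(v[!is_acc], 2)
      if (stats::sd(v) == 0) {
        stat <- p <- NA_real_
      } else {
        t <- mann_whitney_u(v[is_acc], v[!is_acc])
        stat <- t$statistic; p <- t$p_value
      }
    } else {
      summ_a <- sprintf("Yes: %d (%.0f%%)", sum(v[is_acc]),
                        100 * mean(v[is_acc]))
      summ_r <- sprintf("Yes: %d (%.0f%%)", sum(v[!is_acc]),
                        100 * mean(v[!is_acc]))
      tab <- rbind(c(sum(v[is_acc]), sum(v[is_acc] == 0)),
                   c(sum(v[!is_acc]), sum(v[!is_acc] == 0)))
      if (any(colSums(tab) == 0)) {
        stat <- p <- NA_real_
      } else {
        t <- chi_squared(tab)
        stat <- t$statistic; p <- t$p_value
      }
    }
    data.frame(variable = schema$name[j], type = kind,
               accepted = summ_a, rejected = summ_r,
               statistic = stat, p_value = p,
               p_display = if (!is.na(p) && p < 0.10) sprintf("%.3f", p) else "",
               stringsAsFactors = FALSE)
  })
  if (include_outcomes) {
    for (oc in admission_outcomes()) {
      v <- records[[oc]]
      if (is.logical(v)) {
        tab <- rbind(c(sum(v[is_acc]), sum(!v[is_acc])),
                     c(sum(v[!is_acc]), sum(!v[!is_acc])))
        ok <- !any(colSums(tab) == 0)
        t <- if (ok) chi_squared(tab) else NULL
        rows[[length(rows) + 1L]] <- data.frame(
          variable = oc, type = "binary",
          accepted = sprintf("Yes: %d (%.0f%%)", sum(v[is_acc]),
                             100 * mean(v[is_acc])),
          rejected = sprintf("Yes: %d (%.0f%%)", sum(v[!is_acc]),
                             100 * mean(v[!is_acc])),
          statistic = if (ok) t$statistic else NA_real_,
          p_value = if (ok) t$p_value else NA_real_,
          p_display = if (ok && t$p_value < 0.10) sprintf("%.3f", t$p_value)
                      else "",
          stringsAsFactors = FALSE)
      } else {
        t <- mann_whitney_u(v[is_acc], v[!is_acc])
        rows[[length(rows) + 1L]] <- data.frame(
          variable = oc, type = "continuous",
          accepted = fmt_median_range(v[is_acc], 2),
          rejected = fmt_median_range(v[!is_acc], 2),
          statistic = t$statistic, p_value = t$p_value,
          p_display = if (t$p_value < 0.10) sprintf("%.3f", t$p_value) else "",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
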