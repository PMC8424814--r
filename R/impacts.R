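#' Variable impacts: per-input percentage contributions
#'
#' Ranks each model input by its contribution to predictive performance,
#' reported as percentages normalized to sum to 100. The default method is
#' permutation importance: each variable's column(s) are shuffled (columns in
#' the same schema group jointly, so a multi-column categorical gets one
#' impact), the increase in mean squared prediction error (continuous) or
#' misclassification rate (categorical) against the observed outcomes is
#' averaged over `n_repeats` shuffles, negative raw values are floored at
#' zero, and the result is normalized.
#'
#' The `"sweep"` alternative varies one input at a time over its observed
#' range (eleven quantile steps) while holding every other input at its
#' median, and scores the spread (standard deviation) of the resulting
#' predictions.
#'
#' @param model A `cpi_outcome_model`.
#' @param records Consolidated records with observed outcomes (at least 10).
#' @param n_repeats Shuffles per variable (permutation method).
#' @param seed Integer seed.
#' @param method `"permutation"` or `"sweep"`.
#' @return An object of class `variable_impacts`: data frame with `variable`
#'   and `impact` (percent, descending), with `method`, `n_repeats` and
#'   `seed` attributes.
#' @export
variable_impacts <- function(model, records, n_repeats = 5, seed = 1,
                             method = c("permutation", "sweep")) {
  method <- match.arg(method)
  if (n_repeats < 1) stop("n_repeats must be at least 1")
  if (nrow(records) < 10) stop("need at least 10 records to rank impacts")
  feats <- encode_features(records, model$schema, scaling = model$scaling)
  x <- feats$x
  y <- records[[model$outcome]]
  groups <- unique(model$schema$group)

  err <- if (model$task == "continuous") {
    yv <- as.numeric(y)
    function(xm) mean((predict.grnn(model$grnn, xm) - yv)^2)
  } else {
    yv <- as.character(y)
    function(xm) mean(predict.grnn(model$grnn, xm) != yv)
  }

  raw <- with_seed(seed, {
    if (method == "permutation") {
      base <- err(x)
      vapply(groups, function(g) {
        cols <- model$schema$name[model$schema$group == g]
        mean(vapply(seq_len(n_repeats), function(r) {
          xp <- x
          perm <- sample.int(nrow(x))
          xp[, cols] <- x[perm, cols, drop = FALSE]
          err(xp) - base
        }, numeric(1)))
      }, numeric(1))
    } else {
      med <- apply(x, 2L, stats::median)
      vapply(groups, function(g) {
        cols <- model$schema$name[model$schema$group == g]
        qs <- seq(0, 1, length.out = 11)
        sweep_rows <- matrix(rep(med, length(qs)), nrow = length(qs),
                             byrow = TRUE, dimnames = list(NULL, colnames(x)))
        for (cl in cols) {
          sweep_rows[, cl] <- stats::quantile(x[, cl], probs = qs, names = FALSE)
        }
        pred <- predict.grnn(model$grnn, sweep_rows)
        if (model$task == "categorical") {
          post <- predict.grnn(model$grnn, sweep_rows, type = "posterior")
          pred <- post[, ncol(post)]
        }
        stats::sd(as.numeric(pred))
      }, numeric(1))
    }
  })

  raw <- pmax(raw, 0)
  total <- sum(raw)
  impact <- if (total > 0) 100 * raw / total else rep(0, length(raw))
  out <- data.frame(variable = groups, impact = impact,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$impact, out$variable), ]
  rownames(out) <- NULL
  structure(out, class = c("variable_impacts", "data.frame"),
            method = method, n_repeats = n_repeats, seed = seed)
}

#' Group variable impacts
#'
#' Sums the impacts of related variables (e.g. the rejection-linked scores)
#' into named groups; variables not covered by the map are pooled under
#' `"other"`.
#'
#' @param vi A [variable_impacts()] result.
#' @param groups Named list: group name → character vector of variable names.
#' @return Data frame with `group` and `impact` (percent).
#' @export
grouped_impact <- function(vi, groups) {
  members <- unlist(groups, use.names = FALSE)
  unknown <- setdiff(members, vi$variable)
  if (length(unknown) > 0L) {
    stop("unknown variable(s) in group map: ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(members)) stop("group map assigns a variable twice")
  rows <- lapply(names(groups), function(g) {
    data.frame(group = g,
               impact = sum(vi$impact[vi$variable %in% groups[[g]]]),
               stringsAsFactors = FALSE)
  })
  other <- sum(vi$impact[!vi$variable %in% members])
  rows[[length(rows) + 1L]] <- data.frame(group = "other", impact = other,
                                          stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
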