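#' Stop conditions for bandwidth training
#'
#' Training stops when any condition fires: a maximum number of training
#' cycles (criterion evaluations), a wall-clock budget, or failure to further
#' reduce the leave-one-out error by more than a relative tolerance.
#'
#' @param max_cycles Maximum criterion evaluations (default 1,000,000).
#' @param max_seconds Wall-clock budget in seconds (default 120).
#' @param min_improvement Relative improvement below which refinement stops.
#' @return A list of class `grnn_stop`.
#' @export
grnn_stop_conditions <- function(max_cycles = 1e6, max_seconds = 120,
                                 min_improvement = 1e-6) {
  stopifnot(max_cycles > 0, max_seconds > 0, min_improvement >= 0)
  structure(list(max_cycles = max_cycles, max_seconds = max_seconds,
                 min_improvement = min_improvement), class = "grnn_stop")
}

#' Train/test/holdout split
#'
#' Draws `n_holdout` cross-validation scenarios at random from the full set
#' first, then partitions the remainder into training and testing fractions
#' with largest-remainder rounding. With 684 records and the defaults this
#' gives sizes 544/136/4.
#'
#' @param n Number of records, or a data frame whose rows are split.
#' @param train_fraction,test_fraction Fractions of the post-holdout records;
#'   must sum to 1.
#' @param n_holdout Scenarios set aside before the split (default 4).
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return A list with integer index vectors `train`, `test`, `holdout`
#'   forming a disjoint, exhaustive partition of `1:n`.
#' @export
grnn_split <- function(n, train_fraction = 0.8, test_fraction = 0.2,
                       n_holdout = 4, seed = NULL) {
  if (is.data.frame(n)) n <- nrow(n)
  stopifnot(abs(train_fraction + test_fraction - 1) < 1e-9, n_holdout >= 0)
  if (n < n_holdout + 2) {
    stop("too few records (", n, ") for ", n_holdout,
         " holdout scenarios plus a train/test split")
  }
  with_seed(seed, {
    holdout <- if (n_holdout > 0) sort(sample.int(n, n_holdout)) else integer(0)
    rest <- setdiff(seq_len(n), holdout)
    m <- length(rest)
    raw <- m * c(train_fraction, test_fraction)
    sizes <- floor(raw)
    rem <- m - sum(sizes)
    if (rem > 0) {
      give <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
      sizes[give] <- sizes[give] + 1L
    }
    if (any(sizes < 1)) stop("split produced an empty partition; too few records")
    perm <- sample(rest)
    list(train = sort(perm[seq_len(sizes[1])]),
         test = sort(perm[sizes[1] + seq_len(sizes[2])]),
         holdout = holdout)
  })
}

# Squared Euclidean distances between rows of a and rows of b.
dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

# Bandwidth-weighted squared distances: sigma is a scalar shared bandwidth or
# one bandwidth per feature column (Inf drops a feature from the metric).
# Returns distances already divided by sigma^2, for use with unit-bandwidth
# kernel weights.
dist2_scaled <- function(a, b, sigma) {
  if (length(sigma) == 1L) return(dist2(a, b) / sigma^2)
  keep <- is.finite(sigma)
  if (!any(keep)) return(matrix(0, nrow(a), nrow(b)))
  s <- sigma[keep]
  dist2(sweep(a[, keep, drop = FALSE], 2L, s, "/"),
        sweep(b[, keep, drop = FALSE], 2L, s, "/"))
}

# Kernel weight matrix (rows: queries, cols: exemplars), numerically shifted
# per query row so the nearest exemplar always has weight 1 before
# normalization (exact nearest-exemplar behavior as sigma -> 0).
kernel_weights <- function(d2, sigma) {
  e <- -d2 / (2 * sigma^2)
  shift <- e[cbind(seq_len(nrow(e)), max.col(e, ties.method = "first"))]
  exp(e - shift)
}

grnn_predict_raw <- function(d2, y, sigma, task, class_levels = NULL,
                             class_freq = NULL) {
  w <- kernel_weights(d2, sigma)
  if (task == "continuous") {
    as.numeric((w %*% y) / rowSums(w))
  } else {
    mass <- vapply(class_levels,
                   function(cl) rowSums(w[, y == cl, drop = FALSE]),
                   numeric(nrow(w)))
    if (nrow(w) == 1L) {
      mass <- matrix(mass, nrow = 1, dimnames = list(NULL, class_levels))
    }
    post <- mass / rowSums(mass)
    # ties broken toward the more frequent training class, then lexicographic
    pref <- order(-class_freq, class_levels)
    pick <- apply(mass[, pref, drop = FALSE], 1L, which.max)
    list(class = class_levels[pref][pick], posterior = post)
  }
}

#' Leave-one-out criterion for a candidate bandwidth
#'
#' Mean squared leave-one-out prediction error for continuous targets, or the
#' leave-one-out misclassification rate for categorical ones. Each training
#' row is predicted from all other rows.
#'
#' @param x Numeric feature matrix (training rows).
#' @param y Targets (numeric, or factor/character/logical for categorical).
#' @param sigma Positive bandwidth (scalar or one per feature).
#' @param task `"continuous"` or `"categorical"`.
#' @param groups Optional grouping vector (e.g. admission identifiers): rows
#'   sharing a group are held out together, so a row is never predicted from
#'   its own group. Consolidated records of one admission share their
#'   admission's outcomes, and leave-one-record-out would reward bandwidths
#'   that merely re-find the twin record; grouped leave-out removes that
#'   leakage.
#' @return The criterion value (a single number).
#' @export
grnn_loo <- function(x, y, sigma, task = c("continuous", "categorical"),
                     groups = NULL) {
  task <- match.arg(task)
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (nrow(x) < 2) stop("leave-one-out needs at least two training rows")
  d2s <- dist2_scaled(x, x, sigma)
  d2s <- mask_groups(d2s, groups)
  loo_from_scaled(d2s, y, task)
}

# Inf out the diagonal plus, when groups are given, every same-group pair.
mask_groups <- function(d2, groups) {
  if (is.null(groups)) {
    diag(d2) <- Inf
  } else {
    g <- as.character(groups)
    d2[outer(g, g, "==")] <- Inf
  }
  if (any(rowSums(is.finite(d2)) == 0)) {
    stop("a leave-out group spans every training row; no neighbors remain")
  }
  d2
}

# d2s: bandwidth-scaled squared distances with Inf on the diagonal.
loo_from_scaled <- function(d2s, y, task) {
  if (task == "continuous") {
    pred <- grnn_predict_raw(d2s, y, 1, "continuous")
    mean((pred - y)^2)
  } else {
    yc <- as.character(y)
    lev <- sort(unique(yc))
    freq <- as.numeric(table(factor(yc, levels = lev)))
    pred <- grnn_predict_raw(d2s, yc, 1, "categorical",
                             class_levels = lev, class_freq = freq)
    mean(pred$class != yc)
  }
}

#' Fit a generalized regression network
#'
#' An exemplar-based predictor: every training record becomes a pattern node,
#' and prediction is the Gaussian-kernel-weighted average of the training
#' targets (a numerator and a denominator summation node). The only trained
#' quantity is the kernel bandwidth, selected to minimize the leave-one-out
#' criterion over a 32-point logarithmic grid on \[1e-3, 1e3\] (scaled-feature
#' units) followed by golden-section refinement around the grid optimum.
#' When two candidate bandwidths tie, the smaller wins. Training stops when a
#' [grnn_stop_conditions()] condition fires and records which one.
#'
#' With `per_feature = TRUE`, the shared bandwidth is refined into one
#' bandwidth per input by cyclic coordinate descent on the same leave-one-out
#' criterion (each coordinate tries multiplicative steps around its current
#' value plus dropping the feature entirely, i.e. an infinite bandwidth).
#' This is an automatic-relevance form: inputs that do not help prediction
#' are flattened out of the distance metric, which matters for counterfactual
#' queries (see the package vignette). In per-feature mode criterion ties
#' prefer the larger bandwidth (the smoother model).
#'
#' @param x Numeric feature matrix, or a `cpi_features` object (in which case
#'   its schema and scaling are stored on the model).
#' @param y Training targets.
#' @param task `"continuous"` or `"categorical"`.
#' @param stop Stop conditions.
#' @param bandwidth Skip selection and use this fixed bandwidth (scalar or
#'   one per feature).
#' @param per_feature Refine to one bandwidth per feature (default `FALSE`:
#'   the classical single shared bandwidth).
#' @param relevance_tol Relative leave-out improvement a per-feature
#'   coordinate move must achieve to be accepted; guards against bandwidths
#'   collapsing on chance structure.
#' @param groups Optional grouping vector for the leave-out criterion; see
#'   [grnn_loo()].
#' @return An object of class `grnn`: exemplars, targets, `sigma` (scalar or
#'   per-feature vector), task, class levels/frequencies for categorical
#'   tasks, and training metadata (`cycles`, `seconds`, `criterion`,
#'   `stop_reason`).
#' @export
grnn_fit <- function(x, y, task = c("continuous", "categorical"),
                     stop = grnn_stop_conditions(), bandwidth = NULL,
                     per_feature = FALSE, relevance_tol = 1e-3,
                     groups = NULL) {
  task <- match.arg(task)
  features <- NULL
  if (inherits(x, "cpi_features")) {
    features <- x
    x <- features$x
  }
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least two training rows")
  if (length(y) != nrow(x)) stop("length(y) must match nrow(x)")
  if (all(apply(x, 2L, function(v) stats::sd(v) == 0))) {
    stop("degenerate features: every column has zero variance")
  }
  if (task == "categorical") {
    y <- as.character(y)
    lev <- sort(unique(y))
    freq <- as.numeric(table(factor(y, levels = lev)))
  } else {
    y <- as.numeric(y)
    lev <- freq <- NULL
  }

  t0 <- proc.time()[["elapsed"]]
  cycles <- 0L
  stop_reason <- "converged"
  d2 <- dist2(x, x)
  d2 <- mask_groups(d2, groups)

  crit <- function(sigma) {
    cycles <<- cycles + 1L
    loo_from_scaled(d2 / sigma^2, y, task)
  }
  out_of_budget <- function() {
    if (cycles >= stop$max_cycles) { stop_reason <<- "max_cycles"; TRUE }
    else if (proc.time()[["elapsed"]] - t0 >= stop$max_seconds) {
      stop_reason <<- "max_seconds"; TRUE
    } else FALSE
  }

  if (is.null(bandwidth)) {
    grid <- 10^seq(-3, 3, length.out = 32)
    vals <- rep(NA_real_, length(grid))
    for (i in seq_along(grid)) {
      if (out_of_budget()) break
      vals[i] <- crit(grid[i])
    }
    if (all(is.na(vals))) {
      best_sigma <- grid[1]
      best_val <- NA_real_
    } else {
      best_i <- which.min(vals)   # first minimum -> smaller sigma on ties
      best_sigma <- grid[best_i]
      best_val <- vals[best_i]
      # golden-section refinement on log-sigma between the grid neighbors
      if (stop_reason == "converged") {
        lo <- log(grid[max(1L, best_i - 1L)])
        hi <- log(grid[min(length(grid), best_i + 1L)])
        gr <- (sqrt(5) - 1) / 2
        a <- lo; b <- hi
        c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
        f1 <- crit(exp(c1)); f2 <- crit(exp(c2))
        prev_best <- min(best_val, f1, f2)
        while (!out_of_budget()) {
          if (f1 <= f2) { b <- c2; c2 <- c1; f2 <- f1
            c1 <- b - gr * (b - a); f1 <- crit(exp(c1))
          } else { a <- c1; c1 <- c2; f1 <- f2
            c2 <- a + gr * (b - a); f2 <- crit(exp(c2))
          }
          cur_best <- min(f1, f2)
          if (b - a < 1e-4 ||
              prev_best - cur_best < stop$min_improvement * max(prev_best, 1e-12)) {
            break
          }
          prev_best <- min(prev_best, cur_best)
        }
        # candidates in ascending sigma order so ties pick the smaller
        cand_s <- c(exp(a), exp(c1), exp(c2), exp(b), best_sigma)
        cand_v <- c(crit(exp(a)), f1, f2, crit(exp(b)), best_val)
        ord <- order(cand_s)
        cand_s <- cand_s[ord]; cand_v <- cand_v[ord]
        pick <- which.min(cand_v)
        if (cand_v[pick] <= best_val) {
          best_sigma <- cand_s[pick]
          best_val <- cand_v[pick]
        }
      }
    }
  } else {
    if (any(bandwidth <= 0)) stop("bandwidth must be positive")
    best_sigma <- bandwidth
    cycles <- cycles + 1L
    d2b <- dist2_scaled(x, x, bandwidth)
    d2b <- mask_groups(d2b, groups)
    best_val <- loo_from_scaled(d2b, y, task)
    stop_reason <- "fixed_bandwidth"
  }

  if (per_feature && is.null(bandwidth)) {
    p <- ncol(x)
    sig <- rep(best_sigma, p)
    # per-feature squared-difference matrices; the running total keeps an
    # Inf diagonal so leave-one-out exclusion survives incremental updates
    d2k <- lapply(seq_len(p), function(k) outer(x[, k], x[, k], "-")^2)
    total <- d2 / best_sigma^2   # d2 already has the Inf diagonal
    inv2 <- function(s) ifelse(is.finite(s), 1 / s^2, 0)
    steps <- c(1 / 4, 1 / 2, 2, 4)
    for (sweep_i in 1:5) {
      improved_sweep <- FALSE
      for (k in seq_len(p)) {
        if (out_of_budget()) break
        cand <- unique(c(pmin(pmax(sig[k] * steps, 0.05), 1e3), Inf))
        # larger bandwidths first so criterion ties keep the smoother model;
        # a coordinate move must buy a material (relevance_tol) improvement
        cand <- sort(cand[cand != sig[k]], decreasing = TRUE)
        for (s_new in cand) {
          if (out_of_budget()) break
          delta_c <- inv2(s_new) - inv2(sig[k])
          cycles <- cycles + 1L
          val <- loo_from_scaled(total + delta_c * d2k[[k]], y, task)
          if (val < best_val - relevance_tol * max(best_val, 1e-12)) {
            total <- total + delta_c * d2k[[k]]
            sig[k] <- s_new
            best_val <- val
            improved_sweep <- TRUE
          }
        }
      }
      if (!improved_sweep || out_of_budget()) break
    }
    # backward pruning: drop any feature whose whole contribution to the
    # criterion is immaterial, so irrelevant inputs leave the metric entirely
    # (queries differing only in pruned inputs get identical predictions)
    for (k in order(sig, decreasing = TRUE)) {
      if (!is.finite(sig[k])) next
      if (out_of_budget()) break
      delta_c <- -inv2(sig[k])
      cycles <- cycles + 1L
      val <- loo_from_scaled(total + delta_c * d2k[[k]], y, task)
      if (val <= best_val + relevance_tol * max(best_val, 1e-12)) {
        total <- total + delta_c * d2k[[k]]
        sig[k] <- Inf
        best_val <- min(best_val, val)
      }
    }
    best_sigma <- sig
  }

  structure(list(task = task, exemplars = x, targets = y, sigma = best_sigma,
                 class_levels = lev, class_freq = freq,
                 schema = features$schema, scaling = features$scaling,
                 cycles = cycles,
                 seconds = proc.time()[["elapsed"]] - t0,
                 criterion = best_val, stop_reason = stop_reason),
            class = "grnn")
}

#' Predict from a fitted GRNN
#'
#' Continuous task: the kernel-weighted average of training targets — always a
#' convex combination, so predictions lie within the training target range.
#' Categorical task: the class with the largest kernel mass; posteriors are
#' the normalized per-class masses.
#'
#' @param object A `grnn` model.
#' @param newdata Numeric matrix (or vector for one query) with the training
#'   feature columns, or a `cpi_features` object.
#' @param type For categorical tasks, `"response"` (labels) or `"posterior"`.
#' @param ... Unused.
#' @return Numeric predictions, class labels, or a posterior matrix.
#' @export
predict.grnn <- function(object, newdata, type = c("response", "posterior"),
                         ...) {
  type <- match.arg(type)
  if (inherits(newdata, "cpi_features")) newdata <- newdata$x
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$exemplars)) {
    stop("query has ", ncol(newdata), " columns; model expects ",
         ncol(object$exemplars))
  }
  d2 <- dist2_scaled(newdata, object$exemplars, object$sigma)
  if (object$task == "continuous") {
    grnn_predict_raw(d2, object$targets, 1, "continuous")
  } else {
    out <- grnn_predict_raw(d2, object$targets, 1, "categorical",
                            class_levels = object$class_levels,
                            class_freq = object$class_freq)
    if (type == "posterior") out$posterior else out$class
  }
}

#' Evaluate a GRNN on held-out rows
#'
#' @param model A `grnn`.
#' @param x Feature rows (matrix or `cpi_features`).
#' @param y Observed targets for those rows.
#' @return For continuous tasks: list with `r_squared` (against the observed
#'   mean of the evaluation rows), `rmse` and the `pairs` data frame of
#'   observed/predicted values. For categorical: `accuracy` and a `confusion`
#'   table.
#' @export
grnn_evaluate <- function(model, x, y) {
  if (length(y) == 0L) stop("cannot evaluate on zero rows")
  pred <- predict.grnn(model, x)
  if (model$task == "continuous") {
    y <- as.numeric(y)
    sse <- sum((y - pred)^2)
    sst <- sum((y - mean(y))^2)
    list(r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
         rmse = sqrt(mean((y - pred)^2)),
         pairs = data.frame(observed = y, predicted = pred))
  } else {
    y <- as.character(y)
    list(accuracy = mean(pred == y),
         confusion = table(observed = factor(y, levels = model$class_levels),
                           predicted = factor(pred,
                                              levels = model$class_levels)))
  }
}
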