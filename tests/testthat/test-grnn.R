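make_grnn <- function(x, y, sigma) {
  structure(list(task = "continuous", exemplars = as.matrix(x),
                 targets = y, sigma = sigma,
                 class_levels = NULL, class_freq = NULL),
            class = "grnn")
}

test_that("predictions match a brute-force kernel-sum oracle to 1e-12", {
  for (case in 1:20) {
    set.seed(case)
    n <- sample(2:20, 1)
    p <- sample(1:4, 1)
    x <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    q <- matrix(rnorm(5 * p), 5, p)
    sigma <- runif(1, 0.2, 3)
    m <- make_grnn(x, y, sigma)
    expect_equal(predict(m, q), oracle_nw(q, x, y, sigma),
                 tolerance = 1e-12)
    # per-feature bandwidths, including a dropped feature
    sig_vec <- runif(p, 0.2, 3)
    if (p > 1) sig_vec[1] <- Inf
    m2 <- make_grnn(x, y, sig_vec)
    expect_equal(predict(m2, q), oracle_nw(q, x, y, sig_vec),
                 tolerance = 1e-12)
  }
})

test_that("a single exemplar is returned exactly for any bandwidth", {
  m <- make_grnn(matrix(c(0.3, -1.2), 1, 2), 7.5, 0.01)
  expect_equal(predict(m, c(0.3, -1.2)), 7.5)
  expect_equal(predict(m, c(50, 50)), 7.5)   # weights renormalize to 1
})

test_that("a symmetric query averages its two exemplars", {
  m <- make_grnn(matrix(c(0, 1), 2, 1), c(0, 1), 0.8)
  expect_equal(predict(m, matrix(0.5)), 0.5)
})

test_that("bandwidth limits: nearest exemplar as sigma -> 0, mean as sigma -> Inf", {
  set.seed(1)
  x <- matrix(rnorm(12), 6, 2)
  y <- rnorm(6)
  tiny <- make_grnn(x, y, 1e-9)
  expect_equal(predict(tiny, x), y, tolerance = 1e-9)
  huge <- make_grnn(x, y, 1e9)
  expect_equal(predict(huge, matrix(rnorm(2), 1, 2)), mean(y),
               tolerance = 1e-9)
})

test_that("predictions are convex combinations of training targets", {
  set.seed(2)
  x <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  m <- make_grnn(x, y, 0.5)
  q <- matrix(rnorm(300), 100, 3)
  p <- predict(m, q)
  expect_true(all(p >= min(y) - 1e-12 & p <= max(y) + 1e-12))
})

test_that("exemplar order does not change predictions", {
  set.seed(3)
  x <- matrix(rnorm(24), 8, 3)
  y <- rnorm(8)
  q <- matrix(rnorm(9), 3, 3)
  perm <- sample(8)
  expect_equal(predict(make_grnn(x, y, 0.7), q),
               predict(make_grnn(x[perm, ], y[perm], 0.7), q))
})

test_that("classification picks the largest kernel mass with frequency tie-break", {
  x <- matrix(c(0, 1), 2, 1)
  y <- c("no", "yes")
  m <- structure(list(task = "categorical", exemplars = x, targets = y,
                      sigma = 1, class_levels = c("no", "yes"),
                      class_freq = c(1, 1)), class = "grnn")
  expect_identical(predict(m, matrix(0.1)), "no")
  expect_identical(predict(m, matrix(0.9)), "yes")
  post <- predict(m, matrix(0.5), type = "posterior")
  expect_equal(unname(post[1, ]), c(0.5, 0.5))
  # exact tie goes to the more frequent training class
  m$class_freq <- c(1, 3)
  expect_identical(predict(m, matrix(0.5)), "yes")
})

test_that("the leave-one-out criterion matches a hand-rolled computation", {
  set.seed(4)
  x <- matrix(rnorm(10), 5, 2)
  y <- rnorm(5)
  sigma <- 0.9
  manual <- mean(vapply(1:5, function(i) {
    (oracle_nw(x[i, , drop = FALSE], x[-i, , drop = FALSE], y[-i], sigma) -
       y[i])^2
  }, numeric(1)))
  expect_equal(grnn_loo(x, y, sigma, "continuous"), manual,
               tolerance = 1e-12)
})

test_that("grouped leave-out excludes an admission's twin record", {
  # three twin pairs: identical features within a pair, shared outcome, so
  # plain leave-one-record-out copies the twin's answer and scores ~zero
  x <- matrix(c(0, 0, 5, 5, 9, 9), 6, 1)
  y <- c(1, 1, 3, 3, 2, 2)
  groups <- c("g1", "g1", "g2", "g2", "g3", "g3")
  ungrouped <- grnn_loo(x, y, 0.3, "continuous")
  grouped <- grnn_loo(x, y, 0.3, "continuous", groups = groups)
  expect_lt(ungrouped, 1e-6)
  expect_gt(grouped, 1)       # must now reach across to another admission
  expect_error(grnn_loo(x, y, 0.3, "continuous", groups = rep("g", 6)),
               "no neighbors")
})

test_that("fitting selects a bandwidth and records its stopping reason", {
  set.seed(5)
  x <- matrix(runif(40), 20, 2)
  y <- sin(4 * x[, 1]) + 0.1 * rnorm(20)
  m <- grnn_fit(x, y, task = "continuous")
  expect_s3_class(m, "grnn")
  expect_true(m$sigma > 0)
  expect_identical(m$stop_reason, "converged")
  expect_equal(m$criterion, grnn_loo(x, y, m$sigma, "continuous"),
               tolerance = 1e-12)
  capped <- grnn_fit(x, y, task = "continuous",
                     stop = grnn_stop_conditions(max_cycles = 10))
  expect_identical(capped$stop_reason, "max_cycles")
  expect_lte(capped$cycles, 13L)  # the refinement bracket finishes its pair
})

test_that("per-feature relevance drops uninformative inputs", {
  set.seed(6)
  n <- 80
  x <- cbind(sig = runif(n), noise1 = rnorm(n), noise2 = rnorm(n))
  y <- sin(6 * x[, 1]) + 0.05 * rnorm(n)
  m <- grnn_fit(x, y, task = "continuous", per_feature = TRUE)
  expect_identical(length(m$sigma), 3L)
  expect_true(is.finite(m$sigma[1]))
  expect_true(any(!is.finite(m$sigma[2:3])))
  # a pruned input no longer moves predictions
  q <- matrix(c(0.5, 0, 0), 1, 3)
  q2 <- q
  dropped <- which(!is.finite(m$sigma))[1]
  q2[dropped] <- 100
  expect_equal(predict(m, q), predict(m, q2), tolerance = 1e-12)
})

test_that("fixed bandwidths skip selection entirely", {
  set.seed(7)
  x <- matrix(rnorm(20), 10, 2)
  y <- rnorm(10)
  m <- grnn_fit(x, y, task = "continuous", bandwidth = 0.66)
  expect_identical(m$stop_reason, "fixed_bandwidth")
  expect_equal(m$sigma, 0.66)
})

test_that("degenerate inputs are rejected", {
  expect_error(grnn_fit(matrix(1, 5, 2), rnorm(5), "continuous"),
               "zero variance")
  expect_error(grnn_fit(matrix(rnorm(4), 2, 2), rnorm(3), "continuous"),
               "length")
  m <- make_grnn(matrix(rnorm(6), 3, 2), rnorm(3), 1)
  expect_error(predict(m, matrix(0, 1, 3)), "columns")
})

test_that("the split is a disjoint exhaustive partition at the study sizes", {
  s <- grnn_split(684, seed = 123)
  expect_identical(lengths(s[c("train", "test", "holdout")]),
                   c(train = 544L, test = 136L, holdout = 4L))
  expect_identical(sort(c(s$train, s$test, s$holdout)), 1:684)
  expect_identical(grnn_split(684, seed = 123), s)
  expect_false(identical(grnn_split(684, seed = 124), s))
  expect_error(grnn_split(4, n_holdout = 4), "too few")
})

test_that("evaluation reports goodness of fit against observed outcomes", {
  set.seed(8)
  x <- matrix(rnorm(20), 10, 2)
  y <- rnorm(10)
  perfect <- make_grnn(x, y, 1e-9)
  ev <- grnn_evaluate(perfect, x, y)
  expect_equal(ev$r_squared, 1, tolerance = 1e-9)
  expect_equal(ev$rmse, 0, tolerance = 1e-6)
  expect_identical(nrow(ev$pairs), 10L)
})
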