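test_that("the signed-rank p-value matches full sign enumeration", {
  for (case in 1:5) {
    set.seed(case)
    d <- round(rnorm(6), 3)
    d <- d + seq_along(d) * 1e-4          # force distinct absolute values
    got <- paired_continuous_test(d)
    expect_equal(got$p_value, oracle_signed_rank_p(d), tolerance = 1e-12)
    expect_identical(got$n, 6L)
  }
})

test_that("zero differences are dropped before ranking", {
  d <- c(0, 0.5, -0.2, 0, 0.3)
  with_zeros <- paired_continuous_test(d)
  without <- paired_continuous_test(c(0.5, -0.2, 0.3))
  expect_identical(with_zeros$n, 3L)
  expect_equal(with_zeros$p_value, without$p_value)
  degenerate <- paired_continuous_test(rep(0, 10))
  expect_identical(degenerate$p_value, 1)
  expect_identical(degenerate$n, 0L)
  expect_error(paired_continuous_test(numeric(0)), "at least one")
})

test_that("large samples switch to the corrected normal approximation", {
  set.seed(10)
  d <- rnorm(200, mean = 0.1)
  got <- paired_continuous_test(d)
  ref <- suppressWarnings(stats::wilcox.test(d, exact = FALSE,
                                             correct = TRUE))
  expect_equal(got$p_value, ref$p.value)
})

test_that("McNemar continuity correction is clamped at symmetry", {
  r <- paired_categorical_test(6, 1)
  expect_equal(r$statistic, (abs(6 - 1) - 1)^2 / 7)
  sym <- paired_categorical_test(4, 4)
  expect_identical(sym$statistic, 0)
  expect_identical(sym$p_value, 1)
  none <- paired_categorical_test(0, 0)
  expect_identical(none$p_value, 1)
  expect_error(paired_categorical_test(-1, 2), "non-negative")
})

test_that("reassignment is pure, idempotent, and checks its fields", {
  d <- small_synth(seed = 3, n_patients = 30)
  cons <- consolidate_dataset(d$cpi, d$admissions)
  before <- cons
  out <- reassign(cons)
  expect_identical(cons, before)
  expect_true(all(out$status == "accepted"))
  expect_true(all(out$rejection == 0))
  expect_identical(reassign(out), out)
  other <- setdiff(names(cons), c("status", "rejection"))
  expect_identical(out[other], cons[other])
  expect_error(reassign(cons, list(not_a_field = 1)), "not_a_field")
  ext <- reassign(cons, reassignment_policy("extended"))
  expect_true(all(ext$combined_cp_success == 1))
  expect_true(all(ext$physician_rejection == 0))
})

test_that("an empty policy yields identical scenarios and p = 1", {
  d <- small_synth(seed = 3, n_patients = 30)
  cons <- consolidate_dataset(d$cpi, d$admissions)
  m <- fit_outcome_model(cons, "losta",
                         stop = grnn_stop_conditions(max_cycles = 200))
  cf <- run_counterfactual(m, cons, reassignment_policy("none"))
  expect_identical(cf$predictions$factual, cf$predictions$counterfactual)
  expect_identical(cf$mean_difference, 0)
  expect_identical(cf$test$p_value, 1)
  expect_identical(cf$n_edited, 0L)
  expect_true(is.na(cf$mean_difference_edited))
})

test_that("record order does not change the paired comparison", {
  d <- small_synth(seed = 4, n_patients = 30)
  cons <- consolidate_dataset(d$cpi, d$admissions)
  m <- fit_outcome_model(cons, "losta",
                         stop = grnn_stop_conditions(max_cycles = 200))
  cf1 <- run_counterfactual(m, cons)
  set.seed(1)
  shuffled <- cons[sample(nrow(cons)), ]
  cf2 <- run_counterfactual(m, shuffled)
  expect_equal(cf2$mean_difference, cf1$mean_difference)
  expect_equal(cf2$test$p_value, cf1$test$p_value)
  expect_equal(cf2$mean_difference_edited, cf1$mean_difference_edited)
})

test_that("the edited-record mean targets the affected admissions", {
  d <- small_synth(seed = 5, n_patients = 40)
  cons <- consolidate_dataset(d$cpi, d$admissions)
  m <- fit_outcome_model(cons, "losta",
                         stop = grnn_stop_conditions(max_cycles = 200))
  cf <- run_counterfactual(m, cons)
  edited <- cons$status != "accepted" | cons$rejection != 0
  diff <- cf$predictions$factual - cf$predictions$counterfactual
  expect_identical(cf$n_edited, sum(edited))
  expect_equal(cf$mean_difference_edited, mean(diff[edited]))
  expect_equal(cf$mean_difference, mean(diff))
  # untouched records predict identically under both scenarios
  expect_equal(diff[!edited], rep(0, sum(!edited)), tolerance = 1e-12)
})

test_that("categorical outcomes are compared through discordant pairs", {
  d <- small_synth(seed = 6, n_patients = 60)
  cons <- consolidate_dataset(d$cpi, d$admissions)
  m <- fit_outcome_model(cons, "readmitted_30d",
                         stop = grnn_stop_conditions(max_cycles = 200))
  cf <- run_counterfactual(m, cons)
  expect_identical(cf$task, "categorical")
  b <- cf$discordant[["to_positive"]]
  cc <- cf$discordant[["to_negative"]]
  ref <- paired_categorical_test(b, cc)
  expect_equal(cf$test$p_value, ref$p_value)
})

test_that("outcome models refuse unknown outcomes and foreign models", {
  d <- small_synth(seed = 3, n_patients = 20)
  cons <- consolidate_dataset(d$cpi, d$admissions)
  expect_error(fit_outcome_model(cons, "lostb"), "unknown outcome")
  expect_error(run_counterfactual(list(), cons), "cpi_outcome_model")
})

test_that("a model round-trips through JSON with identical predictions", {
  d <- small_synth(seed = 7, n_patients = 30)
  cons <- consolidate_dataset(d$cpi, d$admissions)
  m <- fit_outcome_model(cons, "losta",
                         stop = grnn_stop_conditions(max_cycles = 200))
  path <- tempfile(fileext = ".json")
  write_outcome_model_json(m, path)
  back <- read_outcome_model_json(path)
  expect_equal(predict(back, cons), predict(m, cons), tolerance = 1e-12)
  expect_error(read_outcome_model_json(tempfile()), "not found|cannot")
})
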