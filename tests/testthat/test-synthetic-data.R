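test_that("the same seed reproduces the dataset bit for bit", {
  a <- small_synth(seed = 11)
  b <- small_synth(seed = 11)
  expect_identical(a$cpi, b$cpi)
  expect_identical(a$admissions, b$admissions)
  expect_identical(a$ledger, b$ledger)
  c <- small_synth(seed = 12)
  expect_false(identical(a$admissions$losta, c$admissions$losta))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(small_synth(seed = 5, n_patients = 10))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("ledger counterfactual rule holds exactly at admission scope", {
  d <- small_synth(seed = 2, n_patients = 120, delta_reject = 0.4)
  led <- d$ledger
  expect_equal(led$losta_factual - led$losta_counterfactual,
               0.4 * as.numeric(led$has_rejection), tolerance = 1e-12)
  expect_identical(led$losta_factual, d$admissions$losta)
  expect_identical(led$has_rejection, led$n_rejected > 0L)
})

test_that("per-CPI scope multiplies the effect by the rejected count", {
  d <- small_synth(seed = 2, n_patients = 80, delta_reject = 0.25,
                   delta_scope = "per_cpi")
  led <- d$ledger
  expect_identical(led$losta_factual - led$losta_counterfactual,
                   0.25 * as.numeric(led$n_rejected))
})

test_that("a zero effect makes factual and counterfactual stays identical", {
  d <- small_synth(seed = 8, n_patients = 100, delta_reject = 0)
  expect_identical(d$ledger$losta_factual, d$ledger$losta_counterfactual)
})

test_that("stays sit on the half-day grid within the configured support", {
  d <- small_synth(seed = 4, n_patients = 150)
  cf <- d$ledger$losta_counterfactual
  expect_true(all(cf >= 0 & cf <= d$config$losta$max))
  expect_identical(cf * 2, round(cf * 2))
  expect_true(all(d$admissions$losta >= 0))
  expect_true(all(d$admissions$losicua <= d$admissions$los_icu_total + 1e-9))
})

test_that("generated datasets satisfy every validation invariant", {
  for (s in 1:3) {
    d <- small_synth(seed = s, n_patients = 70)
    issues <- validate_dataset(d$cpi, d$admissions)
    expect_identical(sum(issues$severity == "error"), 0L)
  }
})

test_that("dataset shape and marginals match the study conditions", {
  d <- generate_cpi_data(default_synth_config(), seed = 20190101)
  n_pat <- length(unique(d$admissions$patient_id))
  expect_identical(n_pat, 542L)
  expect_gt(nrow(d$admissions), 542)
  expect_lt(nrow(d$admissions), 650)
  expect_gt(nrow(d$cpi), 1300)
  expect_lt(nrow(d$cpi), 2200)

  acc <- mean(d$cpi$accepted)
  expect_gt(acc, 0.78)
  expect_lt(acc, 0.90)

  by_ph <- tapply(d$cpi$accepted, d$cpi$pharmacist_id, mean)
  expect_equal(as.numeric(by_ph[c("CP1", "CP2", "CP3")]),
               c(0.57, 0.95, 0.86), tolerance = 0.12)

  expect_equal(mean(d$admissions$non_green_antibiotic), 0.481,
               tolerance = 0.15)
  expect_equal(mean(d$admissions$polypharmacy_ge8), 0.175, tolerance = 0.25)
  expect_identical(sum(d$admissions$tricyclic), 0L)

  med_losta <- median(d$admissions$losta)
  expect_gte(med_losta, 0.5)
  expect_lte(med_losta, 3)
})

test_that("risk flags co-occur through the latent frailty", {
  d <- generate_cpi_data(default_synth_config(), seed = 20190101)
  a <- d$admissions
  common <- c("non_green_antibiotic", "high_alert_med", "multi_comorbidity",
              "renal")
  cors <- combn(common, 2, function(p) cor(a[[p[1]]], a[[p[2]]]))
  expect_gt(mean(cors), 0.02)
})

test_that("configuration validation rejects malformed settings", {
  expect_error(default_synth_config(no_such_field = 1), "no_such_field")
  expect_error(default_synth_config(delta_reject = -1), "delta_reject")
  expect_error(default_synth_config(delta_scope = "cpi"), "delta_scope")
  expect_error(default_synth_config(phase_ii_prob = 1.4), "phase_ii_prob")
})

test_that("the dataset summary covers outcomes and flags in display form", {
  d <- small_synth(seed = 6, n_patients = 40)
  s <- summarize_dataset(d)
  expect_true(all(c("losta", "cost", "total_cpi", "accepted",
                    "polypharmacy_ge8") %in% s$variable))
  expect_match(s$summary[s$variable == "losta"], "\\(")
  expect_match(s$summary[s$variable == "accepted"], "Yes: ")
})
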