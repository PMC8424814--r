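test_that("provider rates are accepted fractions over the study period", {
  cpi <- data.frame(
    pharmacist_id = c("a", "a", "b", "b", "b"),
    physician_id = c("x", "y", "x", "x", "z"),
    accepted = c(TRUE, FALSE, TRUE, TRUE, FALSE))
  r <- compute_provider_rates(cpi)
  expect_equal(r$pharmacist_success[["a"]], 0.5)
  expect_equal(r$pharmacist_success[["b"]], 2 / 3)
  expect_equal(r$physician_rejection[["x"]], 0)
  expect_equal(r$physician_rejection[["y"]], 1)
  expect_equal(r$physician_rejection[["z"]], 1)
  expect_error(compute_provider_rates(cpi[0, ]), "empty")
})

test_that("score arithmetic matches hand-computed values", {
  rates <- structure(list(
    pharmacist_success = c(p1 = 0.9, p2 = 0.5),
    physician_rejection = c(m1 = 0.2, m2 = 0.4)), class = "provider_rates")
  cpi <- data.frame(
    admission_id = rep("A1", 4),
    pharmacist_id = c("p1", "p2", "p1", "p2"),
    physician_id = c("m1", "m1", "m2", "m2"),
    accepted = c(TRUE, TRUE, TRUE, FALSE),
    complexity_code = c(1, 0, 0.5, 1),
    intention_code = c(1, 1, 0, 1),
    domain_code = c(1, 1, 1, 1),
    drug_prescribing_step = c(TRUE, FALSE, FALSE, TRUE),
    consult_initiated = c(FALSE, FALSE, FALSE, FALSE),
    outcomes_driven = c(TRUE, TRUE, FALSE, FALSE))
  adm <- data.frame(admission_id = "A1", n_diagnoses = 4L,
                    n_diagnoses_revised = 1L)
  s <- compute_scores(cpi, rates, adm)
  expect_equal(s$problem_complexity, mean(c(1, 0, 0.5, 1)))
  expect_equal(s$problem_intention, 0.75)
  expect_equal(s$clinical_domain, 1)
  expect_equal(s$prescribing_step, 0.5)
  expect_equal(s$consultancy, 0)
  expect_equal(s$outcomes_driven, 0.5)
  expect_equal(s$rejection, 0.25)
  expect_equal(s$combined_cp_success, mean(c(0.9, 0.5, 0.9, 0.5)))
  expect_equal(s$physician_rejection, mean(c(0.2, 0.2, 0.4, 0.4)))
  expect_equal(s$diagnosis_revision, 0.25)
})

test_that("two pharmacists with rates 0.9 and 0.5 combine to 0.7", {
  rates <- structure(list(
    pharmacist_success = c(p1 = 0.9, p2 = 0.5),
    physician_rejection = c(m1 = 0)), class = "provider_rates")
  cpi <- data.frame(
    admission_id = c("A1", "A1"), pharmacist_id = c("p1", "p2"),
    physician_id = c("m1", "m1"), accepted = c(TRUE, TRUE),
    complexity_code = c(1, 1), intention_code = c(1, 1),
    domain_code = c(1, 1), drug_prescribing_step = c(FALSE, FALSE),
    consult_initiated = c(FALSE, FALSE), outcomes_driven = c(FALSE, FALSE))
  adm <- data.frame(admission_id = "A1", n_diagnoses = 1L,
                    n_diagnoses_revised = 0L)
  expect_equal(compute_scores(cpi, rates, adm)$combined_cp_success, 0.7)
})

test_that("a provider missing from the rates is reported by name", {
  rates <- structure(list(pharmacist_success = c(p1 = 1),
                          physician_rejection = c(m1 = 0)),
                     class = "provider_rates")
  cpi <- data.frame(
    admission_id = "A1", pharmacist_id = "p9", physician_id = "m1",
    accepted = TRUE, complexity_code = 1, intention_code = 1,
    domain_code = 1, drug_prescribing_step = FALSE,
    consult_initiated = FALSE, outcomes_driven = FALSE)
  adm <- data.frame(admission_id = "A1", n_diagnoses = 1L,
                    n_diagnoses_revised = 0L)
  expect_error(compute_scores(cpi, rates, adm), "p9")
})

test_that("an admission consolidates into per-status records", {
  r <- tiny_registry()
  rates <- compute_provider_rates(r$cpi)
  a1 <- consolidate_admission(r$cpi[r$cpi$admission_id == "A001", ],
                              r$admissions[1, ], rates)
  expect_identical(nrow(a1), 2L)
  expect_identical(sort(a1$status), c("accepted", "rejected"))
  expect_identical(a1$total_cpi, c(4L, 4L))
  expect_identical(a1$phase, c("I", "I"))
  acc <- a1[a1$status == "accepted", ]
  rej <- a1[a1$status == "rejected", ]
  # type flags OR-aggregate within the status subgroup
  expect_true(acc$change_dose)   # CPI 1 had a dose change
  expect_true(rej$change_dose)   # the rejected CPI 3 had one too
  expect_true(acc$safety_related)
  expect_false(rej$safety_related)
  # mixed scope: descriptive scores over the subgroup, rejection over all CPI
  expect_equal(acc$problem_complexity, mean(c(1, 0, 1)))
  expect_equal(rej$problem_complexity, 0.5)
  expect_equal(acc$rejection, 0.25)
  expect_equal(rej$rejection, 0.25)

  a2 <- consolidate_admission(r$cpi[r$cpi$admission_id == "A002", ],
                              r$admissions[2, ], rates)
  expect_identical(a2$status, "accepted")
  expect_identical(a2$phase, "II")
})

test_that("score scopes change exactly the scores they claim to", {
  r <- tiny_registry()
  rates <- compute_provider_rates(r$cpi)
  cpi1 <- r$cpi[r$cpi$admission_id == "A001", ]
  sub <- consolidate_admission(cpi1, r$admissions[1, ], rates,
                               score_scope = "subgroup")
  expect_equal(sub$rejection[sub$status == "accepted"], 0)
  expect_equal(sub$rejection[sub$status == "rejected"], 1)
  adm <- consolidate_admission(cpi1, r$admissions[1, ], rates,
                               score_scope = "admission")
  expect_equal(adm$problem_complexity,
               rep(mean(cpi1$complexity_code), 2))
  expect_equal(adm$rejection, c(0.25, 0.25))
})

test_that("consolidation counts equal the subgroup census and scores stay in [0, 1]", {
  score_cols <- c("problem_complexity", "problem_intention", "clinical_domain",
                  "prescribing_step", "consultancy", "outcomes_driven",
                  "rejection", "combined_cp_success", "physician_rejection",
                  "diagnosis_revision")
  for (s in 1:4) {
    d <- small_synth(seed = s, n_patients = 30)
    cons <- consolidate_dataset(d$cpi, d$admissions)
    census <- nrow(unique(data.frame(a = d$cpi$admission_id,
                                     s = d$cpi$accepted)))
    expect_identical(nrow(cons), census)
    for (sc in score_cols) {
      expect_true(all(cons[[sc]] >= 0 & cons[[sc]] <= 1))
    }
  }
})

test_that("re-consolidating consolidated records is refused", {
  d <- small_synth(seed = 1, n_patients = 20)
  cons <- consolidate_dataset(d$cpi, d$admissions)
  expect_error(consolidate_dataset(cons, d$admissions), "already consolidated")
})

test_that("consolidated tables survive a write/read round trip", {
  d <- small_synth(seed = 5, n_patients = 25)
  cons <- consolidate_dataset(d$cpi, d$admissions)
  path <- tempfile(fileext = ".csv")
  write_consolidated(cons, path)
  back <- read_consolidated(path)
  expect_s3_class(back, "cpi_consolidated")
  expect_equal(as.data.frame(back), as.data.frame(cons), tolerance = 1e-9)
})
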