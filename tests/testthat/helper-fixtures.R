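# Handmade three-admission registry with known consolidation arithmetic.
#
# A001 (patient P001, phase I):  4 CPI, 1 rejected (order 3).
# A002 (patient P002, phase II): 2 CPI, both accepted.
# A003 (patient P003, phase I):  1 CPI, rejected.
tiny_registry <- function() {
  n <- 7L
  cpi <- data.frame(
    patient_id = c("P001", "P001", "P001", "P001", "P002", "P002", "P003"),
    admission_id = c("A001", "A001", "A001", "A001", "A002", "A002", "A003"),
    cpi_order = c(1L, 2L, 3L, 4L, 1L, 2L, 1L),
    phase = c("I", "I", "I", "I", "II", "II", "I"),
    pharmacist_id = c("CP1", "CP2", "CP1", "CP2", "CP2", "CP1", "CP1"),
    physician_id = c("MD1", "MD1", "MD2", "MD2", "MD1", "MD2", "MD1"),
    accepted = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  for (f in cpimpact:::cpi_type_flags()) cpi[[f]] <- rep(FALSE, n)
  cpi$change_dose <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  cpi$safety_related <- c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)
  cpi$complexity_code <- c(1, 0, 0.5, 1, 0.5, 0.5, 1)
  cpi$intention_code <- c(1, 1, 0, 1, 1, 0, 1)
  cpi$domain_code <- c(1, 1, 1, 0, 1, 1, 1)
  cpi$consult_initiated <- c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  cpi$outcomes_driven <- c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  cpi <- cpi[, cpimpact:::cpi_columns()]

  admissions <- data.frame(
    patient_id = c("P001", "P002", "P003"),
    admission_id = c("A001", "A002", "A003"),
    age_years = c(60, 8, 86),
    gender = c("M", "F", "F"),
    nationality = c("Jordanian", "Jordanian", "Other"),
    age_group = c("adult", "pediatric", "adult"),
    critical = c(TRUE, FALSE, FALSE),
    elderly_gt84 = c(FALSE, FALSE, TRUE),
    insured = c(TRUE, TRUE, FALSE),
    los_before_index = c(2, 0, 1.5),
    los_icu_before_index = c(1, 0, 0),
    stringsAsFactors = FALSE)
  for (f in cpimpact:::admission_risk_flags()) {
    admissions[[f]] <- c(FALSE, FALSE, FALSE)
  }
  admissions$polypharmacy_ge8 <- c(TRUE, FALSE, TRUE)
  admissions$renal <- c(TRUE, FALSE, FALSE)
  admissions$n_diagnoses <- c(4L, 1L, 2L)
  admissions$n_diagnoses_revised <- c(1L, 0L, 2L)
  admissions$los_total <- c(7, 2, 5.5)
  admissions$los_icu_total <- c(3, 0, 0)
  admissions$losta <- c(5, 2, 4)
  admissions$losicua <- c(2, 0, 0)
  admissions$readmitted_30d <- c(FALSE, FALSE, TRUE)
  admissions$died <- c(FALSE, FALSE, FALSE)
  admissions$cost <- c(2900, 1200, 2100)
  admissions <- admissions[, cpimpact:::admission_columns()]

  list(cpi = cpi, admissions = admissions)
}

# Small synthetic registry for structural tests (fast to generate).
small_synth <- function(seed = 1, n_patients = 60, delta_reject = 0.4, ...) {
  generate_cpi_data(default_synth_config(n_patients = n_patients,
                                         delta_reject = delta_reject, ...),
                    seed = seed)
}

# Brute-force Nadaraya-Watson oracle: explicit double loop over queries and
# exemplars, no matrix algebra shared with the implementation under test.
oracle_nw <- function(queries, exemplars, y, sigma) {
  sig <- if (length(sigma) == 1L) rep(sigma, ncol(exemplars)) else sigma
  vapply(seq_len(nrow(queries)), function(i) {
    num <- 0
    den <- 0
    for (j in seq_len(nrow(exemplars))) {
      d2 <- 0
      for (k in seq_len(ncol(exemplars))) {
        if (is.finite(sig[k])) {
          d2 <- d2 + ((queries[i, k] - exemplars[j, k]) / sig[k])^2
        }
      }
      w <- exp(-d2 / 2)
      num <- num + w * y[j]
      den <- den + w
    }
    num / den
  }, numeric(1))
}

# Exact two-sided signed-rank p-value by enumeration of all sign assignments.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# A miniature planted-signal study: the outcome is generated from exactly
# one input plus tiny noise, with nine pure-noise companion inputs.
planted_model <- function(seed, n = 100, p = 10) {
  set.seed(seed)
  records <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(records) <- paste0("v", seq_len(p))
  records$admission_id <- sprintf("A%03d", seq_len(n))
  records$status <- "accepted"
  records$losta <- records$v1 + 0.05 * rnorm(n)
  schema <- data.frame(name = paste0("v", seq_len(p)),
                       source = paste0("v", seq_len(p)),
                       kind = "continuous", level = NA_character_,
                       group = paste0("v", seq_len(p)),
                       stringsAsFactors = FALSE)
  model <- fit_outcome_model(records, "losta", schema = schema,
                             stop = grnn_stop_conditions(max_cycles = 200))
  list(model = model, records = records)
}

# Keep one consolidated record per admission (seeded random pick), so the
# accepted and rejected groups are independent samples of admissions.
one_record_per_admission <- function(cons, seed) {
  set.seed(seed)
  keep <- vapply(split(seq_len(nrow(cons)), cons$admission_id),
                 function(ix) if (length(ix) == 1L) ix else sample(ix, 1L),
                 integer(1))
  out <- cons[sort(keep), ]
  rownames(out) <- NULL
  out
}
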