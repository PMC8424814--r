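#' Default configuration for the synthetic CPI registry generator
#'
#' The defaults emulate an eight-month CPI registry from a 100-bed acute-care
#' hospital: about 542 patients, 574 admissions and 1700 CPI; a three-person
#' clinical pharmacy team with per-pharmacist acceptance probabilities 0.57,
#' 0.95 and 0.86 and workload shares proportional to 256/475/963, giving an
#' expected overall acceptance near 84%; admission-level risk-flag prevalences
#' matching the registry's published marginals (e.g. polypharmacy ≈ 17.5%,
#' non-green antibiotics ≈ 48%); a right-skewed post-index length of stay
#' (LOSTA) discretized to half days with median 1–2 and support 0–30; and a
#' configurable additive causal effect `delta_reject` (days of extra LOSTA
#' when an admission contains at least one rejected CPI), defaulting to 0.4.
#'
#' Risk flags within an admission are positively correlated through a shared
#' latent frailty scalar via a Gaussian copula, so marginal prevalences equal
#' the configured values exactly in expectation while comorbidities co-occur.
#'
#' @param n_patients Number of patients.
#' @param delta_reject Days added to the post-index stay of an admission
#'   containing at least one rejected CPI (the generator's causal effect).
#' @param seed Default seed used by [generate_cpi_data()] when none is given.
#' @param ... Overrides for any other configuration field (see the returned
#'   list for names).
#' @return An object of class `synth_config`.
#' @export
default_synth_config <- function(n_patients = 542, delta_reject = 0.4,
                                 seed = 20190101, ...) {
  cfg <- list(
    n_patients = n_patients,
    readmission_window_prob = 0.06,   # second admission inside the study window
    cpi_per_admission = list(size = 0.9, mu = 1.95, min = 1, max = 38),
    phase_ii_prob = 0.5,
    age = list(adult_prob = 0.74,
               adult = list(min = 18, max = 92, shape1 = 1.6, shape2 = 1.9),
               pediatric = list(min = 0.05, max = 17, shape1 = 0.8, shape2 = 1.5)),
    gender_male_prob = 0.55,
    nationality_jordanian_prob = 0.92,
    insured_prob = 0.67,
    critical_prob = 0.30,
    risk_prevalence = c(
      anticholinergic = 0.003, antiarrhythmic = 0.015, dementia = 0.069,
      anemia = 0.051, heart_failure = 0.034, two_antihypertensives = 0.082,
      three_antihypertensives = 0.032, beta_blocker = 0.110,
      benzodiazepine = 0.039, tricyclic = 0.000, non_green_antibiotic = 0.481,
      surgical = 0.108, polypharmacy_ge8 = 0.175, multi_comorbidity = 0.278,
      vascular = 0.089, acei_arb = 0.107, diuretic = 0.094, renal = 0.196,
      liver = 0.037, high_alert_med = 0.387),
    frailty_rho = 0.25,               # copula correlation among risk flags
    diagnoses = list(mean_extra = 1.2, revision_prob = 0.10),
    pharmacists = data.frame(
      id = c("CP1", "CP2", "CP3"),
      acceptance_prob = c(0.57, 0.95, 0.86),
      weight = c(256, 475, 963) / 1694,
      stringsAsFactors = FALSE),
    n_physicians = 40,
    physician_propensity = list(shape = 4, rate = 4),  # gamma, mean 1
    cpi_flag_prob = c(
      non_drug = 0.25, change_form = 0.09, change_dose = 0.50,
      change_frequency = 0.38, change_route = 0.16, change_duration = 0.08,
      safety_related = 0.20, efficacy_related = 0.25, stop_medication = 0.18,
      add_medication = 0.14, drug_prescribing_step = 0.50,
      miscellaneous = 0.37, not_determined = 0.04),
    complexity_prob = c(simple = 0.15, follow_up = 0.15, complex = 0.70),
    intention_problem_prob = 0.85,
    domain_clinical_prob = 0.90,
    consult_prob = 0.16,
    outcomes_driven_prob = 0.25,
    losta = list(meanlog = log(1.2), sdlog = 1.0, max = 30,
                 coef = c(critical = 1.5, polypharmacy_ge8 = 0.8,
                          multi_comorbidity = 0.7, renal = 0.5),
                 frailty_coef = 0.6),
    delta_reject = delta_reject,
    delta_scope = "admission",        # or "per_cpi": delta per rejected CPI
    los_before = list(meanlog = log(1.2), sdlog = 0.8, max = 38),
    icu = list(meanlog = log(1.0), sdlog = 0.9),
    cost = list(intercept = 600, slope = 320, sd = 900, min = 94),
    readmission = list(intercept = stats::qlogis(0.15), frailty_coef = 0.5,
                       losta_coef = 0.03),
    mortality = list(intercept = stats::qlogis(0.015), frailty_coef = 0.9,
                     critical_coef = 1.0),
    seed = seed
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  chk_prob <- function(p, name) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
      stop("configuration field '", name, "' must lie in [0, 1]")
    }
  }
  chk_prob(cfg$readmission_window_prob, "readmission_window_prob")
  chk_prob(cfg$phase_ii_prob, "phase_ii_prob")
  chk_prob(cfg$risk_prevalence, "risk_prevalence")
  chk_prob(cfg$pharmacists$acceptance_prob, "pharmacists$acceptance_prob")
  chk_prob(cfg$cpi_flag_prob, "cpi_flag_prob")
  chk_prob(cfg$consult_prob, "consult_prob")
  if (cfg$delta_reject < 0) stop("configuration field 'delta_reject' must be >= 0")
  if (cfg$n_patients < 1) stop("configuration field 'n_patients' must be >= 1")
  if (!cfg$delta_scope %in% c("admission", "per_cpi")) {
    stop("configuration field 'delta_scope' must be 'admission' or 'per_cpi'")
  }
  if (abs(sum(cfg$complexity_prob) - 1) > 1e-9) {
    stop("configuration field 'complexity_prob' must sum to 1")
  }
  invisible(cfg)
}

round_half_day <- function(x) round(x * 2) / 2

rlnorm_capped <- function(n, meanlog, sdlog, max) {
  pmin(stats::rlnorm(n, meanlog, sdlog), max)
}

#' Generate a synthetic CPI registry
#'
#' Draws patients, admissions and per-CPI records under a [default_synth_config()]
#' and returns them together with a ground-truth ledger holding, for every
#' admission, whether it contains a rejected CPI and what its post-index stay
#' (LOSTA) would have been had every CPI been accepted. By construction the
#' counterfactual LOSTA equals the factual LOSTA minus the configured causal
#' effect for admissions with a rejection (minus the effect times the number
#' of rejected CPI when `delta_scope = "per_cpi"`), and equals it exactly
#' otherwise — which is what lets downstream estimators be tested for
#' parameter recovery.
#'
#' @param config A `synth_config`.
#' @param seed Integer seed; defaults to `config$seed`. The same seed always
#'   reproduces the same dataset bit for bit.
#' @return An object of class `synth_cpi_data`: list with data frames `cpi`,
#'   `admissions`, `ledger` and the `config` used.
#' @export
generate_cpi_data <- function(config = default_synth_config(),
                              seed = config$seed) {
  validate_synth_config(config)
  with_seed(seed, {
    n_pat <- config$n_patients
    patient_id <- sprintf("P%04d", seq_len(n_pat))
    n_adm_per_pat <- 1L + stats::rbinom(n_pat, 1L, config$readmission_window_prob)
    pat_of_adm <- rep(seq_len(n_pat), n_adm_per_pat)
    n_adm <- length(pat_of_adm)
    admission_id <- sprintf("A%04d", seq_len(n_adm))

    # demographics
    adult <- stats::runif(n_adm) < config$age$adult_prob
    a <- config$age$adult; p <- config$age$pediatric
    age <- ifelse(adult,
                  a$min + (a$max - a$min) * stats::rbeta(n_adm, a$shape1, a$shape2),
                  p$min + (p$max - p$min) * stats::rbeta(n_adm, p$shape1, p$shape2))
    gender <- ifelse(stats::runif(n_adm) < config$gender_male_prob, "M", "F")
    nationality <- ifelse(stats::runif(n_adm) < config$nationality_jordanian_prob,
                          "Jordanian", "Other")
    insured <- stats::runif(n_adm) < config$insured_prob
    critical <- stats::runif(n_adm) < config$critical_prob

    # correlated risk flags through a latent frailty scalar (Gaussian copula:
    # marginals stay exactly at the configured prevalences)
    frailty <- stats::rnorm(n_adm)
    rho <- config$frailty_rho
    prev <- config$risk_prevalence
    flags <- matrix(FALSE, n_adm, length(prev),
                    dimnames = list(NULL, names(prev)))
    for (k in seq_along(prev)) {
      u <- stats::pnorm(sqrt(rho) * frailty +
                          sqrt(1 - rho) * stats::rnorm(n_adm))
      flags[, k] <- u < prev[k]
    }

    n_diag <- 1L + stats::rpois(n_adm, config$diagnoses$mean_extra)
    n_diag_rev <- stats::rbinom(n_adm, n_diag, config$diagnoses$revision_prob)

    phase <- ifelse(stats::runif(n_adm) < config$phase_ii_prob, "II", "I")

    # CPI counts and per-CPI draws
    cc <- config$cpi_per_admission
    n_cpi <- pmin(cc$max, cc$min + stats::rnbinom(n_adm, size = cc$size, mu = cc$mu))
    total_cpi <- sum(n_cpi)
    adm_of_cpi <- rep(seq_len(n_adm), n_cpi)

    ph_idx <- sample.int(nrow(config$pharmacists), total_cpi, replace = TRUE,
                         prob = config$pharmacists$weight)
    physician_id <- sprintf("MD%02d", sample.int(config$n_physicians,
                                                 total_cpi, replace = TRUE))
    pp <- config$physician_propensity
    propensity <- stats::rgamma(config$n_physicians, shape = pp$shape,
                                rate = pp$rate)
    p_rej <- pmin(1, (1 - config$pharmacists$acceptance_prob[ph_idx]) *
                    propensity[as.integer(substring(physician_id, 3))])
    accepted <- stats::runif(total_cpi) >= p_rej

    flag_mat <- sapply(names(config$cpi_flag_prob), function(f) {
      stats::runif(total_cpi) < config$cpi_flag_prob[[f]]
    })
    complexity <- sample(c(0, 0.5, 1), total_cpi, replace = TRUE,
                         prob = config$complexity_prob)
    cpi <- data.frame(
      patient_id = patient_id[pat_of_adm][adm_of_cpi],
      admission_id = admission_id[adm_of_cpi],
      cpi_order = unlist(lapply(n_cpi, seq_len)),
      phase = phase[adm_of_cpi],
      pharmacist_id = config$pharmacists$id[ph_idx],
      physician_id = physician_id,
      accepted = accepted,
      stringsAsFactors = FALSE)
    cpi <- cbind(cpi, as.data.frame(flag_mat))
    cpi$complexity_code <- complexity
    cpi$intention_code <- as.numeric(stats::runif(total_cpi) <
                                       config$intention_problem_prob)
    cpi$domain_code <- as.numeric(stats::runif(total_cpi) <
                                    config$domain_clinical_prob)
    cpi$consult_initiated <- stats::runif(total_cpi) < config$consult_prob
    cpi$outcomes_driven <- stats::runif(total_cpi) < config$outcomes_driven_prob
    cpi <- cpi[, cpi_columns()]

    n_rejected <- tapply(!cpi$accepted, factor(cpi$admission_id,
                                               levels = admission_id), sum)
    n_rejected <- as.integer(n_rejected)
    has_rej <- n_rejected > 0L

    # outcomes: counterfactual (all-accepted) LOSTA first, then add the effect
    lo <- config$losta
    base <- rlnorm_capped(n_adm, lo$meanlog, lo$sdlog, lo$max)
    lin <- rep(0, n_adm)
    for (nm in names(lo$coef)) {
      lin <- lin + lo$coef[[nm]] *
        (if (nm == "critical") critical else flags[, nm])
    }
    lin <- lin + lo$frailty_coef * frailty
    losta_cf <- pmin(lo$max, round_half_day(pmax(0, base + lin)))
    delta_units <- if (config$delta_scope == "admission") as.numeric(has_rej)
                   else n_rejected
    losta <- losta_cf + config$delta_reject * delta_units

    lb <- config$los_before
    los_before <- round_half_day(rlnorm_capped(n_adm, lb$meanlog, lb$sdlog, lb$max))
    los_before[stats::runif(n_adm) < 0.25] <- 0   # index CPI on admission day
    icu_before <- ifelse(critical,
      pmin(los_before,
           round_half_day(rlnorm_capped(n_adm, config$icu$meanlog,
                                        config$icu$sdlog, lb$max))),
      0)
    losicua <- ifelse(critical,
      pmin(losta, round_half_day(rlnorm_capped(n_adm, config$icu$meanlog,
                                               config$icu$sdlog, lo$max))),
      0)
    los_total <- los_before + losta
    los_icu_total <- icu_before + losicua

    co <- config$cost
    cost <- pmax(co$min, co$intercept + co$slope * los_total +
                   stats::rnorm(n_adm, 0, co$sd))
    re <- config$readmission
    readmit <- stats::runif(n_adm) <
      stats::plogis(re$intercept + re$frailty_coef * frailty +
                      re$losta_coef * losta)
    mo <- config$mortality
    died <- stats::runif(n_adm) <
      stats::plogis(mo$intercept + mo$frailty_coef * frailty +
                      mo$critical_coef * critical)

    admissions <- data.frame(
      patient_id = patient_id[pat_of_adm],
      admission_id = admission_id,
      age_years = age,
      gender = gender,
      nationality = nationality,
      age_group = ifelse(adult, "adult", "pediatric"),
      critical = critical,
      elderly_gt84 = age > 84,
      insured = insured,
      los_before_index = los_before,
      los_icu_before_index = icu_before,
      stringsAsFactors = FALSE)
    admissions <- cbind(admissions, as.data.frame(flags))
    admissions$n_diagnoses <- n_diag
    admissions$n_diagnoses_revised <- n_diag_rev
    admissions$los_total <- los_total
    admissions$los_icu_total <- los_icu_total
    admissions$losta <- losta
    admissions$losicua <- losicua
    admissions$readmitted_30d <- readmit
    admissions$died <- died
    admissions$cost <- cost
    admissions <- admissions[, admission_columns()]

    ledger <- data.frame(
      patient_id = admissions$patient_id,
      admission_id = admission_id,
      n_cpi = n_cpi,
      n_rejected = n_rejected,
      has_rejection = has_rej,
      losta_factual = losta,
      losta_counterfactual = losta_cf,
      stringsAsFactors = FALSE)

    structure(list(cpi = cpi, admissions = admissions, ledger = ledger,
                   config = config),
              class = "synth_cpi_data")
  })
}

#' Summarize a dataset in registry display conventions
#'
#' Continuous variables as `median (min–max)`, booleans as `Yes: n (p%)` —
#' the layout used for eyeball comparison against published marginal tables.
#'
#' @param dataset A `synth_cpi_data` object or a list with `cpi` and
#'   `admissions` data frames.
#' @return A data frame with columns `variable`, `type`, `summary`.
#' @export
summarize_dataset <- function(dataset) {
  adm <- dataset$admissions
  cpi <- dataset$cpi
  if (nrow(adm) == 0L) stop("cannot summarize an empty dataset")
  rows <- list()
  add <- function(variable, type, summary) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, type = type, summary = summary,
      stringsAsFactors = FALSE)
  }
  fmt_bool <- function(v) {
    sprintf("Yes: %d (%.0f%%)", sum(v), 100 * mean(v))
  }
  for (v in c("age_years", "los_before_index", "los_icu_before_index",
              "los_total", "los_icu_total", "losta", "losicua", "cost")) {
    add(v, "continuous", fmt_median_range(adm[[v]]))
  }
  for (v in c(admission_risk_flags(), "critical", "elderly_gt84", "insured",
              "readmitted_30d", "died")) {
    add(v, "boolean", fmt_bool(adm[[v]]))
  }
  n_cpi <- as.integer(table(factor(cpi$admission_id,
                                   levels = adm$admission_id)))
  add("total_cpi", "continuous", fmt_median_range(n_cpi))
  add("accepted", "boolean", fmt_bool(cpi$accepted))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
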