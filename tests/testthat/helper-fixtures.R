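# Hand-built fixture constructors and direct hurdle-model row simulators
# used across the test files.

fx_patient <- function(patient_id, age = 45, sex = "female", region = "East",
                       ethnicity = "White", imd_quintile = "3",
                       bmi_category = "Normal weight", asthma = FALSE,
                       mental_health = FALSE, n_comorbidities = 0L,
                       prior_covid_hospitalisation = FALSE,
                       n_vaccine_doses = "2",
                       positive_test_before_index = FALSE,
                       registration_start = as.Date("2015-01-01"),
                       registration_end = as.Date("2023-01-31"),
                       death_date = as.Date(NA),
                       longcovid_diagnosis_date = as.Date(NA),
                       longcovid_resolved_date = as.Date(NA),
                       practice_id = "PR001") {
  tibble::tibble(
    patient_id = patient_id, age = as.integer(age), sex = sex, region = region,
    ethnicity = ethnicity, imd_quintile = imd_quintile,
    bmi_category = bmi_category, asthma = asthma, mental_health = mental_health,
    n_comorbidities = as.integer(n_comorbidities),
    prior_covid_hospitalisation = prior_covid_hospitalisation,
    n_vaccine_doses = n_vaccine_doses,
    positive_test_before_index = positive_test_before_index,
    registration_start = as.Date(registration_start),
    registration_end = as.Date(registration_end),
    death_date = as.Date(death_date),
    longcovid_diagnosis_date = as.Date(longcovid_diagnosis_date),
    longcovid_resolved_date = as.Date(longcovid_resolved_date),
    practice_id = practice_id
  )
}

fx_patients <- function(...) dplyr::bind_rows(...)

fx_event <- function(patient_id, date, care_type, code = NA_character_,
                     cost = NA_real_, discharge_date = as.Date(NA)) {
  tibble::tibble(
    patient_id = patient_id, date = as.Date(date), care_type = care_type,
    code = code, cost = cost, discharge_date = as.Date(discharge_date)
  )
}

fx_events <- function(...) dplyr::bind_rows(...)

# Direct simulation of AnalysisRow tables from the hurdle model (no event
# streams, no deduplication): the correctly specified setting for the
# two-part estimator, with exact known truths.
sim_hurdle_rows <- function(n, p_comparator = 0.6, p_exposed = 0.9,
                            base_mu = 10, log_rr = log(1.5), alpha = 0.8,
                            exposed_frac = 1 / 6,
                            cost_mean = 500, log_cost_ratio = 0,
                            gamma_shape = 1.5, covariate = TRUE,
                            seed = 1) {
  set.seed(seed)
  exposed <- stats::runif(n) < exposed_frac
  x <- if (covariate) stats::rbinom(n, 1, 0.5) else integer(n)
  p <- ifelse(exposed, p_exposed, p_comparator)
  h <- stats::runif(n) < p
  mu <- base_mu * exp(log_rr * exposed + 0.2 * x)
  y <- integer(n)
  if (any(h)) y[h] <- hurdlecohort:::rtrunc_count(sum(h), mu[h], alpha)
  cost <- numeric(n)
  cm <- cost_mean * exp(log_cost_ratio * exposed)
  cost[h] <- stats::rgamma(sum(h), shape = gamma_shape, scale = cm[h] / gamma_shape)
  tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    set_id = rep(seq_len(ceiling(n / 6)), each = 6)[seq_len(n)],
    group = ifelse(exposed, "exposed", "comparator"),
    period = "contemporary",
    follow_up_days = 365.25,
    total_visits = y,
    total_cost = cost,
    sex = ifelse(x == 1, "female", "male")
  )
}

# Stacked two-period rows from the hurdle model for DID tests;
# exposed contemporary rates are multiplied by exp(log_did).
sim_did_rows <- function(n_person, p = 0.75, base_mu = 10, log_rr = log(1.4),
                         log_did = 0, alpha = 0.8, seed = 1) {
  set.seed(seed)
  exposed <- rep(seq_len(n_person) %% 6 == 0, 2)
  period <- rep(c("historical", "contemporary"), each = n_person)
  mu <- base_mu * exp(log_rr * exposed +
    log_did * exposed * (period == "contemporary"))
  h <- stats::runif(2 * n_person) < p
  y <- integer(2 * n_person)
  y[h] <- hurdlecohort:::rtrunc_count(sum(h), mu[h], alpha)
  tibble::tibble(
    patient_id = rep(sprintf("P%05d", seq_len(n_person)), 2),
    set_id = rep(rep(seq_len(ceiling(n_person / 6)), each = 6)[seq_len(n_person)], 2),
    group = ifelse(exposed, "exposed", "comparator"),
    period = period,
    follow_up_days = 365.25,
    total_visits = y
  )
}

# spec with no adjustment covariates (group only)
spec_group_only <- function(outcome = "total_visits", ...) {
  model_spec(outcome = outcome, covariates = character(0), ...)
}
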