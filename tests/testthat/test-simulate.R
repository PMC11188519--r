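# Synthetic cohort generator: bookkeeping, determinism, moments and
# effect fidelity.

test_that("population size bookkeeping and input validation", {
  p <- simulation_params(n_exposed = 10, comparator_pool_multiplier = 10, seed = 5)
  pop <- generate_population(p)
  expect_equal(nrow(pop$patients), 110)
  expect_equal(sum(pop$truth$patients$group == "exposed"), 10)
  expect_equal(sum(pop$truth$patients$group == "comparator_pool"), 100)
  expect_true(all(pop$patients$age >= 18))
  expect_error(simulation_params(n_exposed = 0), "positive integer")
  expect_error(simulation_params(n_exposed = 2.5), "positive integer")
  expect_error(simulation_params(p_nonzero_exposed = 1.2), "\\[0, 1\\]")
})

test_that("identical parameters and seed give identical output", {
  p <- simulation_params(n_exposed = 50, seed = 99)
  a <- generate_population(p)
  b <- generate_population(p)
  expect_identical(a$patients, b$patients)
  expect_identical(a$truth$patients, b$truth$patients)
  w <- tibble::tibble(
    patient_id = a$patients$patient_id,
    start = as.Date("2021-01-01"), end = as.Date("2022-01-01")
  )
  e1 <- generate_event_stream(a$patients, w, p, "contemporary")
  e2 <- generate_event_stream(b$patients, w, p, "contemporary")
  expect_identical(e1, e2)
})

test_that("exposed group carries the heavier comorbidity burden", {
  p <- simulation_params(n_exposed = 3000, comparator_pool_multiplier = 3, seed = 7)
  pop <- generate_population(p)
  exposed <- pop$truth$patients$group == "exposed"
  frac_any <- function(sel) mean(pop$patients$n_comorbidities[sel] >= 1)
  expect_gt(frac_any(exposed), frac_any(!exposed))
  expect_gt(
    mean(pop$patients$prior_covid_hospitalisation[exposed]),
    mean(pop$patients$prior_covid_hospitalisation[!exposed])
  )
})

test_that("degenerate hurdle produces empty event streams", {
  p <- simulation_params(
    n_exposed = 20, p_nonzero_exposed = 0, p_nonzero_comparator = 0, seed = 3
  )
  pop <- generate_population(p)
  w <- tibble::tibble(
    patient_id = pop$patients$patient_id,
    start = as.Date("2021-01-01"), end = as.Date("2022-01-01")
  )
  ev <- generate_event_stream(pop$patients, w, p, "contemporary")
  expect_equal(nrow(ev), 0)
})

test_that("event stream rejects empty windows and unknown period labels", {
  p <- simulation_params(n_exposed = 5, seed = 3)
  pop <- generate_population(p)
  w <- tibble::tibble(
    patient_id = pop$patients$patient_id[1],
    start = as.Date("2021-01-01"), end = as.Date("2021-01-01")
  )
  expect_error(generate_event_stream(pop$patients, w, p, "contemporary"), "empty")
  w$end <- as.Date("2021-06-01")
  expect_error(generate_event_stream(pop$patients, w, p, "postmodern"), "period")
})

test_that("null effects give equal group means within Monte-Carlo error", {
  p <- simulation_params(
    n_exposed = 2500, comparator_pool_multiplier = 1,
    rate_ratio_true = 1, did_effect_true = 0,
    p_nonzero_exposed = 0.7, p_nonzero_comparator = 0.7,
    covariate_effect_map = c(female = 0), seed = 21
  )
  pop <- generate_population(p)
  w <- tibble::tibble(
    patient_id = pop$patients$patient_id,
    start = as.Date("2021-01-01"), end = as.Date("2022-01-01")
  )
  ev <- generate_event_stream(pop$patients, w, p, "contemporary")
  counts <- table(factor(ev$patient_id, levels = pop$patients$patient_id))
  cnt <- as.numeric(counts)
  exposed <- pop$truth$patients$group == "exposed"
  m_e <- mean(cnt[exposed])
  m_c <- mean(cnt[!exposed])
  se <- sqrt(
    stats::var(cnt[exposed]) / sum(exposed) +
      stats::var(cnt[!exposed]) / sum(!exposed)
  )
  expect_lt(abs(m_e - m_c), 3 * se)
})

test_that("generated non-zero counts are overdispersed when alpha > 0", {
  p <- simulation_params(
    n_exposed = 1000, comparator_pool_multiplier = 1,
    base_rate = 12, dispersion_alpha = 1, rate_ratio_true = 1,
    did_effect_true = 0, covariate_effect_map = c(female = 0), seed = 17
  )
  pop <- generate_population(p)
  w <- tibble::tibble(
    patient_id = pop$patients$patient_id,
    start = as.Date("2021-01-01"), end = as.Date("2022-01-01")
  )
  ev <- generate_event_stream(pop$patients, w, p, "contemporary")
  cnt <- as.numeric(table(ev$patient_id)) # non-zero patients only
  expect_gt(stats::var(cnt), mean(cnt))
})

test_that("hurdle probabilities and rate ratio are reproduced at n = 10,000", {
  p <- simulation_params(
    n_exposed = 5000, comparator_pool_multiplier = 1,
    did_effect_true = 0, seed = 31
  )
  pop <- generate_population(p)
  w <- tibble::tibble(
    patient_id = pop$patients$patient_id,
    start = as.Date("2021-01-01"), end = as.Date("2022-01-01")
  )
  ev <- generate_event_stream(pop$patients, w, p, "contemporary")
  has <- pop$patients$patient_id %in% ev$patient_id
  exposed <- pop$truth$patients$group == "exposed"
  for (g in c(TRUE, FALSE)) {
    p_true <- if (g) p$p_nonzero_exposed else p$p_nonzero_comparator
    n_g <- sum(exposed == g)
    se <- sqrt(p_true * (1 - p_true) / n_g)
    expect_lt(abs(mean(has[exposed == g]) - p_true), 3 * se)
  }
  # conditional mean ratio of raw event counts ~ rate_ratio_true, adjusted
  # for the covariate mix via the ground-truth linear predictor
  cnt <- as.numeric(table(factor(ev$patient_id, levels = pop$patients$patient_id)))
  eta <- pop$truth$patients$eta_covariates
  adj <- cnt / exp(eta)
  r_e <- adj[exposed & has]
  r_c <- adj[!exposed & has]
  log_ratio <- log(mean(r_e) / mean(r_c))
  se_log <- sqrt(
    stats::var(r_e) / (length(r_e) * mean(r_e)^2) +
      stats::var(r_c) / (length(r_c) * mean(r_c)^2)
  )
  expect_lt(abs(log_ratio - log(p$rate_ratio_true)), 3 * se_log)
})

test_that("implied effects reflect parameters and arm mixtures", {
  p <- simulation_params(n_exposed = 300, seed = 13)
  pop <- generate_population(p)
  ie <- implied_effects(pop$truth)
  expect_equal(
    unname(ie$odds_ratio),
    (0.961 / 0.039) / (0.75 / 0.25),
    tolerance = 1e-10
  )
  expect_equal(unname(ie$rate_ratio[["contemporary"]]), 1.49 * 1.43, tolerance = 1e-10)
  # deduplication can only attenuate the conditional ratio
  expect_lt(ie$rate_ratio_dedup[["contemporary"]], ie$rate_ratio[["contemporary"]])
  expect_gt(ie$rate_ratio_dedup[["contemporary"]], 1)
  expect_gt(ie$did_estimate, 0)
})
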