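# Table-1 descriptives, imputation, stratified analysis, restrictions.

test_that("chi-square without continuity correction matches the hand formula", {
  pats <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(sprintf("A%03d", 1:100), function(id) {
      fx_patient(id, asthma = as.logical(id %in% sprintf("A%03d", 1:20)))
    })),
    dplyr::bind_rows(lapply(sprintf("B%03d", 1:100), function(id) {
      fx_patient(id, asthma = as.logical(id %in% sprintf("B%03d", 1:10)))
    }))
  )
  group <- rep(c("exposed", "comparator"), each = 100)
  tab <- table_one(pats, group, factors = "asthma")
  # (20,80 | 10,90): sum (O-E)^2/E = 25/15*2 + 25/85*2
  want_stat <- 2 * 25 / 15 + 2 * 25 / 85
  want_p <- stats::pchisq(want_stat, df = 1, lower.tail = FALSE)
  expect_equal(unique(tab$p_value[tab$factor == "asthma"]), want_p, tolerance = 1e-10)
  expect_equal(tab$n_exposed[tab$level == "yes"], 20)
  expect_equal(tab$pct_exposed[tab$level == "yes"], 20.0)
})

test_that("identical group distributions give p = 1 and missing rows are separate", {
  pats <- dplyr::bind_rows(lapply(1:40, function(i) {
    fx_patient(sprintf("P%03d", i), ethnicity = c("White", "Black")[1 + i %% 2])
  }))
  group <- rep(c("exposed", "comparator"), each = 20)
  pats$ethnicity[c(1, 2, 21, 22)] <- NA
  tab <- table_one(pats, group, factors = "ethnicity")
  expect_equal(unique(stats::na.omit(tab$p_value)), 1, tolerance = 1e-9)
  miss <- tab[tab$level == "(missing)", ]
  expect_equal(nrow(miss), 1)
  expect_equal(miss$n_exposed + miss$n_comparator, 4L)
  # percentages recompute from counts among non-missing
  obs <- tab[tab$factor == "ethnicity" & tab$level != "(missing)", ]
  expect_equal(obs$pct_exposed,
    round(100 * obs$n_exposed / sum(obs$n_exposed), 1),
    tolerance = 1e-9
  )
})

test_that("printed cohort table percentages recompute from printed counts", {
  fixture <- readr::read_csv(
    system.file("extdata", "table1_counts.csv", package = "hurdlecohort"),
    show_col_types = FALSE
  )
  got <- recompute_percentages(
    fixture[, c("factor", "level", "n_exposed", "n_comparator")]
  )
  expect_equal(got$pct_exposed, fixture$pct_exposed_printed)
  expect_equal(got$pct_comparator, fixture$pct_comparator_printed)
})

test_that("missing cost imputation replaces only missing values with type means", {
  ev <- fx_events(
    fx_event("A", "2021-01-01", "ae", cost = 100),
    fx_event("B", "2021-01-02", "ae", cost = 300),
    fx_event("C", "2021-01-03", "ae", cost = NA),
    fx_event("D", "2021-01-04", "gp"),
    fx_event("E", "2021-01-05", "outpatient", cost = 80)
  )
  out <- impute_missing_costs(ev)
  expect_equal(out$cost[3], 200)
  expect_equal(out$cost[c(1, 2, 5)], c(100, 300, 80))
  expect_true(is.na(out$cost[4])) # GP events are unit-costed, never imputed
  expect_equal(attr(out, "n_imputed")[["ae"]], 1L)
  expect_equal(mean(out$cost[out$care_type == "ae"]), 200) # type mean preserved

  # no missing costs: identity
  ev2 <- ev[1:2, ]
  expect_equal(impute_missing_costs(ev2)$cost, ev2$cost)

  ev3 <- fx_events(fx_event("A", "2021-01-01", "admission", cost = NA))
  expect_error(impute_missing_costs(ev3), "admission")
})

test_that("stratified analysis: df bookkeeping and saturated equivalence", {
  rows <- sim_hurdle_rows(4000, alpha = 0, seed = 61)
  sp <- model_spec(
    outcome = "total_visits", covariates = "sex", family = "poisson"
  )
  out <- stratified_analysis(rows, sp, stratify_by = "sex")
  expect_equal(nrow(out), 2)
  expect_equal(unique(out$lrt_df), 1)
  expect_true(all(out$lrt_stat_part1 >= 0 & out$lrt_stat_part2 >= 0))

  # the interaction model is saturated in the stratum, so stratum-specific
  # estimates equal separate per-stratum group-only fits
  for (lev in c("female", "male")) {
    sub <- rows[rows$sex == lev, ]
    f <- fit_two_part(sub, spec_group_only(family = "poisson"))
    eff <- effect_estimates(f)
    row <- out[out$stratum == lev, ]
    expect_equal(row$or, eff$estimate[eff$measure == "odds_ratio"], tolerance = 1e-6)
    expect_equal(row$ratio, eff$estimate[eff$measure == "rate_ratio"], tolerance = 1e-6)
  }
})

test_that("stratified analysis detects a real interaction and errors on empty cells", {
  set.seed(62)
  n <- 20000
  g <- rbinom(n, 1, 1 / 6)
  s <- rbinom(n, 1, 0.5)
  log_rr <- ifelse(s == 1, log(2), 0)
  h <- runif(n) < ifelse(g == 1, 0.9, 0.6)
  mu <- 8 * exp(log_rr * g)
  y <- integer(n)
  y[h] <- hurdlecohort:::rtrunc_count(sum(h), mu[h], 0.5)
  rows <- tibble::tibble(
    patient_id = as.character(seq_len(n)), set_id = rep(1:(n / 4), each = 4)[1:n],
    group = ifelse(g == 1, "exposed", "comparator"),
    follow_up_days = 365.25, total_visits = y,
    sex = ifelse(s == 1, "female", "male")
  )
  sp <- model_spec(outcome = "total_visits", covariates = "sex", family = "negbin")
  out <- stratified_analysis(rows, sp, stratify_by = "sex")
  expect_lt(out$lrt_p_part2[1], 0.01)
  fem <- out[out$stratum == "female", ]
  mal <- out[out$stratum == "male", ]
  expect_gt(fem$ratio, 1.7)
  expect_lt(abs(log(mal$ratio)), 0.15)

  rows_bad <- rows[!(rows$group == "exposed" & rows$sex == "male"), ]
  expect_error(stratified_analysis(rows_bad, sp, stratify_by = "sex"), "empty")
  expect_error(stratified_analysis(rows, sp, stratify_by = "region"), "covariates")
})

test_that("cohort restrictions filter as specified", {
  pats <- dplyr::bind_rows(lapply(sprintf("P%02d", 1:10), function(id) {
    fx_patient(id, positive_test_before_index = id %in% sprintf("P%02d", 1:4))
  }))
  ev <- fx_events(
    fx_event("P01", "2020-01-15", "gp"), # inside the prior-consult window
    fx_event("P02", "2019-10-01", "gp"), # before it
    fx_event("P03", "2021-05-01", "gp"),
    fx_event("P03", "2021-06-01", "gp")
  )
  r1 <- apply_restriction(pats, ev, "prior_gp_consult_within_1y")
  expect_equal(r1$patients$patient_id, "P01")
  expect_equal(r1$n_dropped, 9)

  r2 <- apply_restriction(pats, ev, "positive_test_before_index")
  expect_equal(nrow(r2$patients), 4)

  idx <- tibble::tibble(patient_id = "P03", index_date = as.Date("2021-03-01"))
  r3 <- apply_restriction(pats, ev, "drop_first_gp_event", index_dates = idx)
  kept <- r3$events[r3$events$patient_id == "P03", ]
  expect_equal(nrow(kept), 1)
  expect_equal(kept$date, as.Date("2021-06-01"))

  # a person with a single post-index GP visit ends up with zero
  idx1 <- tibble::tibble(patient_id = "P01", index_date = as.Date("2020-01-01"))
  r4 <- apply_restriction(pats, ev, "drop_first_gp_event", index_dates = idx1)
  expect_false(any(r4$events$patient_id == "P01"))

  expect_error(apply_restriction(pats, ev, "no_such_rule"), "valid rules")
})
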