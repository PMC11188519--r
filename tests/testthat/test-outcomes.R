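# Visit counting with same-day deduplication and cost assembly.

test_that("same-day events of one care type count as one visit", {
  ev <- fx_events(
    fx_event("A", "2021-05-01", "prescription", code = "01"),
    fx_event("A", "2021-05-01", "prescription", code = "02"),
    fx_event("A", "2021-05-01", "prescription", code = "01")
  )
  cnt <- count_utilisation(ev, "2021-01-01", "2022-01-01")
  expect_equal(unname(cnt[["prescription"]]), 1)
  expect_equal(unname(cnt[["total"]]), 1)
})

test_that("deduplication is within care type only", {
  ev <- fx_events(
    fx_event("A", "2021-05-01", "gp"),
    fx_event("A", "2021-05-01", "ae", cost = 120)
  )
  cnt <- count_utilisation(ev, "2021-01-01", "2022-01-01")
  expect_equal(unname(cnt[["gp"]]), 1)
  expect_equal(unname(cnt[["ae"]]), 1)
  expect_equal(unname(cnt[["total"]]), 2)
})

test_that("empty streams, out-of-window events and same-day admissions count zero", {
  empty <- fx_event("A", "2021-05-01", "gp")[0, ]
  expect_equal(unname(count_utilisation(empty, "2021-01-01", "2022-01-01")[["total"]]), 0)
  ev <- fx_events(
    fx_event("A", "2020-12-31", "gp"), # before window
    fx_event("A", "2022-01-01", "gp"), # at half-open end
    fx_event("A", "2021-06-01", "admission", discharge_date = "2021-06-01"),
    fx_event("A", "2021-07-01", "admission", discharge_date = "2021-07-03")
  )
  cnt <- count_utilisation(ev, "2021-01-01", "2022-01-01")
  expect_equal(unname(cnt[["gp"]]), 0)
  expect_equal(unname(cnt[["admission"]]), 1)
})

test_that("enlarging the interval never decreases counts", {
  set.seed(55)
  ev <- fx_events(
    tibble::tibble(
      patient_id = "A",
      date = as.Date("2021-01-01") + sample.int(300, 60, replace = TRUE),
      care_type = sample(care_types(), 60, replace = TRUE),
      code = "01", cost = NA_real_, discharge_date = as.Date(NA)
    )
  )
  ev$discharge_date[ev$care_type == "admission"] <-
    ev$date[ev$care_type == "admission"] + 3
  ends <- as.Date("2021-03-01") + c(0, 60, 120, 240)
  prev <- rep(0, 6)
  for (e in ends) {
    cnt <- count_utilisation(ev, "2021-01-01", e)
    expect_true(all(cnt >= prev))
    prev <- cnt
  }
})

test_that("GP visits are costed at the unit price and chapters at raw frequency", {
  uc <- unit_cost_table()
  ev1 <- fx_events(fx_event("A", "2021-05-01", "gp"))
  cnt1 <- count_utilisation(ev1, "2021-01-01", "2022-01-01")
  c1 <- assemble_costs(ev1, cnt1, uc, "2021-01-01", "2022-01-01")
  expect_equal(c1$total_cost, 41)

  # three same-day prescriptions in one chapter: one visit, three items
  uc2 <- unit_cost_table(bnf_chapter_costs = c("03" = 10))
  ev2 <- fx_events(
    fx_event("A", "2021-05-01", "prescription", code = "03"),
    fx_event("A", "2021-05-01", "prescription", code = "03"),
    fx_event("A", "2021-05-01", "prescription", code = "03")
  )
  cnt2 <- count_utilisation(ev2, "2021-01-01", "2022-01-01")
  expect_equal(unname(cnt2[["prescription"]]), 1)
  c2 <- assemble_costs(ev2, cnt2, uc2, "2021-01-01", "2022-01-01")
  expect_equal(c2$prescription_cost, 30)

  empty <- ev1[0, ]
  c0 <- assemble_costs(empty, count_utilisation(empty, "2021-01-01", "2022-01-01"),
    uc, "2021-01-01", "2022-01-01"
  )
  expect_equal(c0$total_cost, 0)
})

test_that("cost assembly validates chapters and cost signs, flags missingness", {
  uc <- unit_cost_table(bnf_chapter_costs = c("01" = 10))
  ev <- fx_events(fx_event("A", "2021-05-01", "prescription", code = "99"))
  cnt <- count_utilisation(ev, "2021-01-01", "2022-01-01")
  expect_error(
    assemble_costs(ev, cnt, uc, "2021-01-01", "2022-01-01"),
    "99"
  )
  ev2 <- fx_events(fx_event("A", "2021-05-01", "ae", cost = -5))
  expect_error(
    assemble_costs(ev2, cnt, uc, "2021-01-01", "2022-01-01"),
    "negative"
  )
  ev3 <- fx_events(
    fx_event("A", "2021-05-01", "ae", cost = 100),
    fx_event("A", "2021-06-01", "ae", cost = NA)
  )
  c3 <- assemble_costs(ev3, cnt, uc, "2021-01-01", "2022-01-01")
  expect_true(c3$cost_missing_flag)
  expect_equal(c3$ae_cost, 100)
})

test_that("analysis rows: bookkeeping, hand-recount, conservation", {
  members <- tibble::tibble(
    set_id = 1L,
    patient_id = c("E1", paste0("C", 1:5)),
    group = c("exposed", rep("comparator", 5)),
    index_date = as.Date("2021-03-01")
  )
  pats <- fx_patients(
    fx_patient("E1", longcovid_diagnosis_date = "2021-03-01"),
    dplyr::bind_rows(lapply(paste0("C", 1:5), fx_patient))
  )
  fu <- compute_follow_up(members, pats)
  ev <- fx_events(
    fx_event("E1", "2021-04-01", "gp"),
    fx_event("E1", "2021-04-01", "gp"), # same-day duplicate
    fx_event("E1", "2021-04-02", "prescription", code = "01"),
    fx_event("E1", "2021-05-10", "ae", cost = 250),
    fx_event("C1", "2021-06-01", "outpatient", cost = 150)
  )
  rows <- build_analysis_rows(members, fu, ev, pats, unit_cost_table(), "contemporary")
  expect_equal(nrow(rows), 6)
  expect_equal(sum(rows$group == "exposed"), 1)
  e1 <- rows[rows$patient_id == "E1", ]
  expect_equal(e1$n_gp, 1)
  expect_equal(e1$total_visits, 3)
  expect_equal(e1$total_cost, 41 + 10 + 250)
  expect_equal(
    rows$total_visits,
    rows$n_gp + rows$n_prescription + rows$n_ae + rows$n_admission + rows$n_outpatient
  )
  expect_equal(rows$gp_cost, 41 * rows$n_gp)
})

test_that("historical rows require registration from March 2019 through index", {
  members <- tibble::tibble(
    set_id = 1L, patient_id = c("A", "B"),
    group = c("exposed", "comparator"), index_date = as.Date("2021-03-01")
  )
  pats <- fx_patients(
    fx_patient("A", longcovid_diagnosis_date = "2021-03-01"),
    fx_patient("B", registration_start = "2020-06-01")
  )
  fu <- compute_follow_up(members, pats)
  ev <- fx_events(
    fx_event("A", "2019-06-01", "gp"),
    fx_event("A", "2020-02-29", "gp"),
    fx_event("A", "2020-03-01", "gp"), # outside the half-open window
    fx_event("B", "2019-06-01", "gp")
  )
  rows <- build_analysis_rows(members, fu, ev, pats, unit_cost_table(), "historical")
  expect_equal(rows$patient_id, "A")
  expect_equal(rows$n_gp, 2)
  expect_equal(rows$follow_up_days, 366) # 2019-03-01 to 2020-03-01 spans a leap day
})

test_that("missing patients abort row building with their ids", {
  members <- tibble::tibble(
    set_id = 1L, patient_id = c("A", "ZZ"),
    group = c("exposed", "comparator"), index_date = as.Date("2021-03-01")
  )
  pats <- fx_patient("A", longcovid_diagnosis_date = "2021-03-01")
  fu <- tibble::tibble(
    patient_id = members$patient_id, set_id = 1L, group = members$group,
    start = members$index_date, end = members$index_date + 365,
    end_reason = "window_end", follow_up_days = 365, zero_length = FALSE
  )
  expect_error(
    build_analysis_rows(members, fu, fx_event("A", "2021-04-01", "gp"), pats,
      unit_cost_table(),
      period = "contemporary"
    ),
    "ZZ"
  )
})
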