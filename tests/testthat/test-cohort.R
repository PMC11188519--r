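# Eligibility, exact matching and follow-up computation.

test_that("eligibility applies age and registration rules with a tally", {
  pats <- fx_patients(
    fx_patient("A", age = 17),
    fx_patient("B", registration_start = "2020-09-01"), # < 90 days before start
    fx_patient("C", registration_start = "2020-08-03"), # exactly 90 days: kept
    fx_patient("D", registration_end = "2020-10-01"), # deregistered before start
    fx_patient("E")
  )
  res <- apply_eligibility(pats, study_start = as.Date("2020-11-01"))
  expect_setequal(res$eligible$patient_id, c("C", "E"))
  tally <- setNames(res$exclusions$n, res$exclusions$reason)
  expect_equal(tally[["age"]], 1)
  expect_equal(tally[["registration"]], 2)
})

test_that("missing registration dates exclude the patient without aborting", {
  pats <- fx_patients(
    fx_patient("A"),
    fx_patient("B", registration_start = NA)
  )
  res <- apply_eligibility(pats)
  expect_equal(res$eligible$patient_id, "A")
  expect_equal(res$exclusions$reason, "incomplete_record")
})

test_that("matching takes exactly the available candidates in a stratum", {
  pats <- fx_patients(
    fx_patient("E1", longcovid_diagnosis_date = "2021-03-01"),
    dplyr::bind_rows(lapply(paste0("C", 1:5), fx_patient))
  )
  m <- match_exposed(pats, ratio = 5, seed = 1)
  expect_equal(sum(m$group == "comparator"), 5)
  expect_equal(unique(m$index_date), as.Date("2021-03-01"))
  expect_error(match_exposed(pats, ratio = 0), ">= 1")
})

test_that("matching is without replacement, in index-date order", {
  # E2 registers after E1's index date, so the two exposed persons compete
  # for the same seven comparators only
  pats <- fx_patients(
    fx_patient("E1", longcovid_diagnosis_date = "2021-03-01"),
    fx_patient("E2",
      longcovid_diagnosis_date = "2021-05-01",
      registration_start = "2021-04-01"
    ),
    dplyr::bind_rows(lapply(paste0("C", 1:7), fx_patient))
  )
  m <- match_exposed(pats, ratio = 5, seed = 2)
  sizes <- table(m$set_id[m$group == "comparator"])
  # first set (earlier index date) takes 5, the second the remaining 2
  expect_equal(as.integer(sizes), c(5, 2))
  first_set <- m$patient_id[m$set_id == 1 & m$group == "exposed"]
  expect_equal(first_set, "E1")
  comp <- m$patient_id[m$group == "comparator"]
  expect_equal(anyDuplicated(comp), 0)
})

test_that("comparators match the exposed stratum exactly and balance holds", {
  p <- simulation_params(n_exposed = 250, comparator_pool_multiplier = 30, seed = 23)
  pop <- generate_population(p)
  # coarsen the strata so every set can be completed (supply per exact-age
  # stratum is otherwise finite by design)
  set.seed(24)
  pop$patients$age <- sample(40:44, nrow(pop$patients), replace = TRUE)
  pop$patients$region <- sample(c("East", "London", "North West"),
    nrow(pop$patients),
    replace = TRUE
  )
  elig <- apply_eligibility(pop$patients)
  m <- match_exposed(elig$eligible, seed = 4)
  joined <- dplyr::inner_join(m, pop$patients, by = "patient_id")
  by_set <- split(joined, joined$set_id)
  same <- vapply(by_set, function(d) {
    length(unique(d$age)) == 1 && length(unique(d$sex)) == 1 &&
      length(unique(d$region)) == 1
  }, logical(1))
  expect_true(all(same))
  # with abundant candidates all sets are complete and the marginals agree
  sizes <- table(joined$set_id[joined$group == "comparator"])
  expect_true(all(sizes == 5))
  tab <- table(joined$age, joined$group)
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.8)
})

test_that("a person diagnosed later can serve as comparator before diagnosis", {
  # C1 registers too late to serve E1, so E2 (diagnosed later) is E1's only
  # possible comparator; C1 then serves E2's own set
  pats <- fx_patients(
    fx_patient("E1", longcovid_diagnosis_date = "2021-03-01"),
    fx_patient("E2", longcovid_diagnosis_date = "2022-06-01"),
    fx_patient("C1", registration_start = "2021-06-01")
  )
  m <- match_exposed(pats, ratio = 5, seed = 1)
  expect_true("E2" %in% m$patient_id[m$group == "comparator" & m$set_id == 1])
  expect_true("E2" %in% m$patient_id[m$group == "exposed"])
  expect_equal(
    m$patient_id[m$group == "comparator" & m$set_id == 2], "C1"
  )
})

test_that("follow-up end is the argmin of the censoring rules", {
  members <- tibble::tibble(
    patient_id = c("A", "B", "C"),
    set_id = 1L,
    group = c("exposed", "comparator", "exposed"),
    index_date = as.Date("2021-01-01")
  )
  pats <- fx_patients(
    fx_patient("A"), # uncensored
    fx_patient("B", longcovid_diagnosis_date = "2021-04-11"), # +100 days
    fx_patient("C",
      longcovid_resolved_date = "2021-07-20", # +200 days
      death_date = "2021-05-31" # +150 days, wins
    )
  )
  fu <- compute_follow_up(members, pats)
  expect_equal(fu$follow_up_days, c(365, 100, 150))
  expect_equal(fu$end_reason, c("window_end", "comparator_diagnosed", "death"))
  # resolved codes censor the exposed only
  members$group <- c("comparator", "exposed", "comparator")
  fu2 <- compute_follow_up(members, pats)
  expect_equal(fu2$end_reason[2], "window_end")
  expect_equal(fu2$end_reason[3], "death")
})

test_that("zero-length follow-up is flagged and admin end is never exceeded", {
  members <- tibble::tibble(
    patient_id = c("A", "B"), set_id = 1L,
    group = "exposed", index_date = as.Date(c("2021-01-01", "2022-12-01"))
  )
  pats <- fx_patients(
    fx_patient("A", death_date = "2021-01-01"),
    fx_patient("B")
  )
  fu <- compute_follow_up(members, pats)
  expect_true(fu$zero_length[1])
  expect_equal(fu$end[2], as.Date("2023-01-31"))
  expect_equal(fu$end_reason[2], "admin_end")
  expect_true(all(fu$end <= as.Date("2023-01-31")))
})
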