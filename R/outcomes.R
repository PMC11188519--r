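# Person-period outcome construction: same-day-deduplicated visit counts
# and assembled costs.

#' Default unit-cost table
#'
#' GP consultations are costed at a flat rate per (deduplicated) visit;
#' prescriptions at a per-item cost by BNF chapter.
#'
#' @param gp_consultation_cost Pounds per GP consultation (default 41, the
#'   2021/22 national average).
#' @param bnf_chapter_costs Named numeric vector, pounds per prescription by
#'   BNF chapter.
#' @return A `unit_cost_table` list.
#' @export
unit_cost_table <- function(gp_consultation_cost = 41,
                            bnf_chapter_costs = c(
                              "01" = 10, "02" = 15, "03" = 8,
                              "04" = 12, "05" = 20
                            )) {
  if (gp_consultation_cost < 0 || any(bnf_chapter_costs < 0)) {
    stop("unit costs must be non-negative", call. = FALSE)
  }
  structure(
    list(
      gp_consultation_cost = gp_consultation_cost,
      bnf_chapter_costs = bnf_chapter_costs
    ),
    class = "unit_cost_table"
  )
}

# restrict events to a half-open interval, dropping malformed dates
interval_events <- function(events, start, end) {
  ok <- !is.na(events$date)
  events <- events[ok & events$date >= start & events$date < end, , drop = FALSE]
  events
}

#' Count healthcare visits per care type with same-day deduplication
#'
#' For each care type, counts the number of *distinct dates* with at least
#' one event of that type inside the half-open interval: multiple same-day
#' contacts of one type (e.g. several prescriptions issued together) count
#' as one visit. Deduplication is within type only, so a GP visit and an
#' A&E attendance on the same day count separately. Admissions count only
#' when the stay exceeds one day (`discharge_date > date`); events outside
#' the interval are ignored.
#'
#' @param events Event tibble for one person (`date`, `care_type`,
#'   optionally `discharge_date`).
#' @param start,end Half-open interval bounds.
#' @return Named numeric vector over [care_types()] plus `total`.
#' @export
count_utilisation <- function(events, start, end) {
  start <- assert_date(start)
  end <- assert_date(end)
  ev <- interval_events(events, start, end)
  if ("discharge_date" %in% names(ev)) {
    adm <- ev$care_type == "admission"
    keep <- !adm | (!is.na(ev$discharge_date) & ev$discharge_date > ev$date)
    ev <- ev[keep, , drop = FALSE]
  }
  counts <- vapply(care_types(), function(tp) {
    length(unique(ev$date[ev$care_type == tp]))
  }, numeric(1))
  c(counts, total = sum(counts))
}

#' Assemble cost components for one person-interval
#'
#' GP cost is the deduplicated GP visit count times the unit consultation
#' cost; prescription cost multiplies the *raw* prescription frequency per
#' BNF chapter (not the deduplicated visit count) by the chapter unit cost;
#' A&E, admission and outpatient costs are the sums of recorded event costs
#' in the interval. Rows with any missing secondary-care cost are flagged.
#'
#' @param events Event tibble for one person.
#' @param counts Output of [count_utilisation()] for the same interval.
#' @param unit_costs A [unit_cost_table()].
#' @param start,end Half-open interval bounds.
#' @return Named list of cost components, `total`, and `cost_missing_flag`.
#' @export
assemble_costs <- function(events, counts, unit_costs, start, end) {
  stopifnot(inherits(unit_costs, "unit_cost_table"))
  ev <- interval_events(events, assert_date(start), assert_date(end))
  if (any(!is.na(ev$cost) & ev$cost < 0)) {
    stop("negative recorded cost", call. = FALSE)
  }
  rx <- ev[ev$care_type == "prescription", , drop = FALSE]
  missing_ch <- setdiff(unique(rx$code), names(unit_costs$bnf_chapter_costs))
  if (length(missing_ch) > 0) {
    stop(sprintf(
      "unit-cost table missing BNF chapters: %s",
      paste(missing_ch, collapse = ", ")
    ), call. = FALSE)
  }
  rx_cost <- if (nrow(rx)) {
    sum(unit_costs$bnf_chapter_costs[rx$code])
  } else {
    0
  }
  sec_cost <- function(tp) {
    x <- ev$cost[ev$care_type == tp]
    list(cost = sum(x, na.rm = TRUE), missing = anyNA(x))
  }
  ae <- sec_cost("ae")
  adm <- sec_cost("admission")
  op <- sec_cost("outpatient")
  gp_cost <- unname(counts["gp"]) * unit_costs$gp_consultation_cost
  list(
    gp_cost = gp_cost,
    prescription_cost = rx_cost,
    ae_cost = ae$cost,
    admission_cost = adm$cost,
    outpatient_cost = op$cost,
    total_cost = gp_cost + rx_cost + ae$cost + adm$cost + op$cost,
    cost_missing_flag = ae$missing || adm$missing || op$missing
  )
}

#' Fixed pre-pandemic observation window for the historical comparison
#'
#' The historical period is the same calendar year, March 2019 to March
#' 2020 (half-open), for every patient regardless of index date.
#'
#' @return Named Date vector with `start` and `end`.
#' @export
historical_window <- function() {
  c(start = as.Date("2019-03-01"), end = as.Date("2020-03-01"))
}

#' Build person-period analysis rows
#'
#' One row per matched-set member per period, carrying follow-up time,
#' per-type deduplicated visit counts, assembled costs and covariates: the
#' unit of two-part modelling. Contemporary rows use each member's censored
#' follow-up interval; historical rows use the fixed window March 2019 -
#' March 2020 (truncated by registration end or death) and exist only for
#' members registered from the start of that window through their index
#' date. Zero-length intervals are excluded (count in attribute
#' `"excluded_zero_length"`).
#'
#' @param members Long matched-set tibble (`set_id`, `patient_id`, `group`,
#'   `index_date`).
#' @param follow_ups Output of [compute_follow_up()] (required for
#'   contemporary rows).
#' @param events Event tibble.
#' @param patients Patient tibble.
#' @param unit_costs A [unit_cost_table()].
#' @param period `"contemporary"` or `"historical"`.
#' @return AnalysisRow tibble.
#' @export
build_analysis_rows <- function(members, follow_ups, events, patients,
                                unit_costs = unit_cost_table(),
                                period = c("contemporary", "historical")) {
  period <- match.arg(period)
  missing_ids <- setdiff(members$patient_id, patients$patient_id)
  if (length(missing_ids) > 0) {
    stop(sprintf(
      "patients missing from patient table: %s",
      paste(utils::head(missing_ids, 10), collapse = ", ")
    ), call. = FALSE)
  }

  if (period == "contemporary") {
    iv <- dplyr::inner_join(
      members, follow_ups[, c("patient_id", "set_id", "start", "end")],
      by = c("patient_id", "set_id")
    )
  } else {
    hw <- historical_window()
    pat <- patients[, c(
      "patient_id", "registration_start", "registration_end", "death_date"
    )]
    iv <- dplyr::inner_join(members, pat, by = "patient_id")
    keep <- iv$registration_start <= hw["start"] &
      iv$registration_end >= iv$index_date
    iv <- iv[keep, , drop = FALSE]
    iv$start <- hw[["start"]]
    iv$end <- pmin(
      hw[["end"]],
      iv$registration_end + 1,
      dplyr::coalesce(iv$death_date, as.Date("9999-12-31"))
    )
  }
  zero_len <- as.numeric(iv$end - iv$start) <= 0
  n_zero <- sum(zero_len)
  iv <- iv[!zero_len, , drop = FALSE]

  # per-member counting; events pre-split by patient for speed
  ok_date <- !is.na(events$date)
  ev_by_pat <- split(events[ok_date, , drop = FALSE], events$patient_id[ok_date])
  empty <- events[0, , drop = FALSE]
  n_iv <- nrow(iv)
  cnt_mat <- matrix(0, n_iv, 6, dimnames = list(NULL, c(care_types(), "total")))
  cost_mat <- matrix(0, n_iv, 6, dimnames = list(NULL, c(
    "gp_cost", "prescription_cost", "ae_cost", "admission_cost",
    "outpatient_cost", "total_cost"
  )))
  miss_flag <- logical(n_iv)
  for (i in seq_len(n_iv)) {
    ev <- ev_by_pat[[iv$patient_id[i]]] %||% empty
    cnt <- count_utilisation(ev, iv$start[i], iv$end[i])
    cst <- assemble_costs(ev, cnt, unit_costs, iv$start[i], iv$end[i])
    cnt_mat[i, ] <- cnt
    cost_mat[i, ] <- c(
      cst$gp_cost, cst$prescription_cost, cst$ae_cost,
      cst$admission_cost, cst$outpatient_cost, cst$total_cost
    )
    miss_flag[i] <- cst$cost_missing_flag
  }
  out <- tibble::tibble(
    patient_id = iv$patient_id, set_id = iv$set_id,
    group = iv$group, period = period,
    follow_up_days = as.numeric(iv$end - iv$start),
    n_gp = as.vector(cnt_mat[, "gp"]),
    n_prescription = as.vector(cnt_mat[, "prescription"]),
    n_ae = as.vector(cnt_mat[, "ae"]),
    n_admission = as.vector(cnt_mat[, "admission"]),
    n_outpatient = as.vector(cnt_mat[, "outpatient"]),
    total_visits = as.vector(cnt_mat[, "total"]),
    gp_cost = as.vector(cost_mat[, "gp_cost"]),
    prescription_cost = as.vector(cost_mat[, "prescription_cost"]),
    ae_cost = as.vector(cost_mat[, "ae_cost"]),
    admission_cost = as.vector(cost_mat[, "admission_cost"]),
    outpatient_cost = as.vector(cost_mat[, "outpatient_cost"]),
    total_cost = as.vector(cost_mat[, "total_cost"]),
    cost_missing_flag = miss_flag
  )
  if (nrow(out) > 0) {
    covars <- patients[, c(
      "patient_id", "age", "sex", "region", "ethnicity", "imd_quintile",
      "bmi_category", "asthma", "mental_health", "n_comorbidities",
      "prior_covid_hospitalisation", "n_vaccine_doses",
      "positive_test_before_index"
    )]
    out <- dplyr::left_join(out, covars, by = "patient_id")
    out$age_cat <- as.character(age_category(out$age))
  }
  attr(out, "excluded_zero_length") <- n_zero
  out
}
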