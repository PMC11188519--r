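# Cohort construction: eligibility, 1:5 exact matching, follow-up.

#' Apply study eligibility rules
#'
#' Retains adults (18+) registered with their practice for at least
#' `min_registration_days` before `study_start` and still registered at
#' `study_start`. Patients with missing registration dates are excluded with
#' reason `"incomplete_record"` rather than aborting. Optionally drops
#' patients of practices flagged as never using a long COVID code.
#'
#' @param patients Patient tibble.
#' @param study_start Study start date (default 2020-11-01).
#' @param min_registration_days Minimum prior registration (default 90; the
#'   boundary is inclusive).
#' @param coding_practices Optional character vector of practice ids that use
#'   long COVID codes; `NULL` (default) keeps all practices.
#' @return List with `eligible` (tibble) and `exclusions` (tibble of
#'   `reason`, `n`, flow-chart style; each patient counted at their first
#'   failing rule).
#' @export
apply_eligibility <- function(patients, study_start = as.Date("2020-11-01"),
                              min_registration_days = 90,
                              coding_practices = NULL) {
  study_start <- assert_date(study_start)
  reason <- rep(NA_character_, nrow(patients))
  if (!is.null(coding_practices) && "practice_id" %in% names(patients)) {
    bad <- !(patients$practice_id %in% coding_practices)
    reason[is.na(reason) & bad] <- "non_coding_practice"
  }
  incomplete <- is.na(patients$registration_start) | is.na(patients$registration_end)
  reason[is.na(reason) & incomplete] <- "incomplete_record"
  under_age <- !is.na(patients$age) & patients$age < 18
  reason[is.na(reason) & (under_age | is.na(patients$age))] <- "age"
  reg_fail <- !incomplete &
    (patients$registration_start > study_start - min_registration_days |
      patients$registration_end < study_start)
  reason[is.na(reason) & reg_fail] <- "registration"

  excl <- table(reason)
  list(
    eligible = patients[is.na(reason), , drop = FALSE],
    exclusions = tibble::tibble(
      reason = names(excl),
      n = as.integer(excl)
    )
  )
}

#' Match exposed patients to comparators 1:ratio on exact strata
#'
#' For each exposed patient (anyone with a long COVID diagnosis date),
#' processed in ascending index-date order, samples without replacement up
#' to `ratio` eligible comparators with identical values of the matching
#' variables who are registered and alive at the index date and not yet
#' diagnosed themselves. Comparators are never reused across sets; ties are
#' broken by seeded random sampling. Each comparator inherits the exposed
#' person's diagnosis date as their index date. A person diagnosed later in
#' the study may serve as a comparator before their own diagnosis.
#'
#' @param eligible Eligible patient tibble (from [apply_eligibility()]).
#' @param ratio Maximum comparators per exposed person (default 5).
#' @param match_vars Exact matching variables (default age, sex, region).
#' @param seed Seed for tie-breaking.
#' @return Long tibble of set members: `set_id`, `patient_id`, `group`
#'   (`"exposed"`/`"comparator"`), `index_date`. Attribute
#'   `"dropped_unmatched"` counts exposed patients with zero available
#'   comparators.
#' @export
match_exposed <- function(eligible, ratio = 5,
                          match_vars = c("age", "sex", "region"),
                          seed = 1L) {
  if (length(ratio) != 1L || is.na(ratio) || ratio < 1) {
    stop("ratio must be >= 1", call. = FALSE)
  }
  stopifnot(all(match_vars %in% names(eligible)))
  set.seed(seed)

  exposed <- eligible[!is.na(eligible$longcovid_diagnosis_date), , drop = FALSE]
  exposed <- exposed[order(exposed$longcovid_diagnosis_date, exposed$patient_id), ,
    drop = FALSE
  ]
  stratum_key <- function(df) {
    do.call(paste, c(lapply(match_vars, function(v) as.character(df[[v]])), sep = "\r"))
  }
  key_all <- stratum_key(eligible)
  by_stratum <- split(seq_len(nrow(eligible)), key_all)
  used <- rep(FALSE, nrow(eligible))

  out <- vector("list", nrow(exposed))
  dropped <- 0L
  for (i in seq_len(nrow(exposed))) {
    idx_date <- exposed$longcovid_diagnosis_date[i]
    cand <- by_stratum[[stratum_key(exposed[i, , drop = FALSE])]]
    ok <- cand[!used[cand] &
      eligible$patient_id[cand] != exposed$patient_id[i] &
      (is.na(eligible$longcovid_diagnosis_date[cand]) |
        eligible$longcovid_diagnosis_date[cand] > idx_date) &
      eligible$registration_start[cand] <= idx_date &
      eligible$registration_end[cand] >= idx_date &
      (is.na(eligible$death_date[cand]) | eligible$death_date[cand] > idx_date)]
    if (length(ok) == 0) {
      dropped <- dropped + 1L
      next
    }
    take <- if (length(ok) <= ratio) ok else sample(ok, ratio)
    used[take] <- TRUE
    out[[i]] <- tibble::tibble(
      set_id = i,
      patient_id = c(exposed$patient_id[i], eligible$patient_id[take]),
      group = c("exposed", rep("comparator", length(take))),
      index_date = idx_date
    )
  }
  res <- dplyr::bind_rows(out)
  res$set_id <- match(res$set_id, unique(res$set_id))
  attr(res, "dropped_unmatched") <- dropped
  res
}

#' Compute censored follow-up from the index date
#'
#' Follow-up runs from the index date to the earliest of death, end of GP
#' registration, receipt of a resolved long COVID code (exposed only), long
#' COVID diagnosis (comparators only), administrative end of follow-up, and
#' the end of the outcome window. Intervals are half-open `[start, end)`;
#' a zero-length interval (e.g. death on the index date) is flagged for
#' exclusion rather than erroring.
#'
#' @param members Long matched-set tibble (`patient_id`, `group`,
#'   `index_date`, optionally `set_id`).
#' @param patients Patient tibble.
#' @param window_days Outcome window length (default 365).
#' @param admin_end Administrative end of follow-up (default 2023-01-31).
#' @return Tibble with `patient_id`, `set_id` (if present), `group`,
#'   `start`, `end`, `end_reason`, `follow_up_days`, `zero_length`.
#' @export
compute_follow_up <- function(members, patients, window_days = 365,
                              admin_end = as.Date("2023-01-31")) {
  admin_end <- assert_date(admin_end)
  pat <- dplyr::left_join(
    members,
    patients[, c(
      "patient_id", "registration_end", "death_date",
      "longcovid_diagnosis_date", "longcovid_resolved_date"
    )],
    by = "patient_id"
  )
  start <- assert_date(pat$index_date)
  n <- nrow(pat)
  far <- as.Date("9999-12-31")
  # deregistration censors only when it precedes the administrative end;
  # a registration running to (or past) admin_end is administrative censoring
  dereg <- dplyr::coalesce(pat$registration_end, far)
  dereg[dereg >= admin_end] <- far
  cand <- cbind(
    death = as.numeric(dplyr::coalesce(pat$death_date, far)),
    deregistration = as.numeric(dereg),
    resolved_code = as.numeric(ifelse(pat$group == "exposed",
      dplyr::coalesce(pat$longcovid_resolved_date, far), far
    )),
    comparator_diagnosed = as.numeric(ifelse(pat$group == "comparator",
      dplyr::coalesce(pat$longcovid_diagnosis_date, far), far
    )),
    admin_end = rep(as.numeric(admin_end), n),
    window_end = as.numeric(start + window_days)
  )
  pick <- apply(cand, 1L, which.min)
  end <- as.Date(cand[cbind(seq_len(n), pick)], origin = "1970-01-01")
  tibble::tibble(
    patient_id = pat$patient_id,
    set_id = if ("set_id" %in% names(pat)) pat$set_id else NA_integer_,
    group = pat$group,
    start = start,
    end = end,
    end_reason = colnames(cand)[pick],
    follow_up_days = as.numeric(end - start),
    zero_length = as.numeric(end - start) <= 0
  )
}
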