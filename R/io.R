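# Delimited-file interfaces: schemas, validated readers, writers.
# All tables are comma-separated UTF-8 with a header row; dates ISO-8601;
# intervals half-open; currency in pounds.

patient_col_types <- function() {
  readr::cols(
    patient_id = readr::col_character(),
    age = readr::col_integer(),
    sex = readr::col_character(),
    region = readr::col_character(),
    ethnicity = readr::col_character(),
    imd_quintile = readr::col_character(),
    bmi_category = readr::col_character(),
    asthma = readr::col_logical(),
    mental_health = readr::col_logical(),
    n_comorbidities = readr::col_integer(),
    prior_covid_hospitalisation = readr::col_logical(),
    n_vaccine_doses = readr::col_character(),
    positive_test_before_index = readr::col_logical(),
    registration_start = readr::col_date(),
    registration_end = readr::col_date(),
    death_date = readr::col_date(),
    longcovid_diagnosis_date = readr::col_date(),
    longcovid_resolved_date = readr::col_date(),
    practice_id = readr::col_character()
  )
}

event_col_types <- function() {
  readr::cols(
    patient_id = readr::col_character(),
    date = readr::col_character(), # validated row-wise, bad dates rejected
    care_type = readr::col_character(),
    code = readr::col_character(),
    cost = readr::col_double(),
    discharge_date = readr::col_date()
  )
}

#' Read and validate the pipeline input tables
#'
#' Reads the patient, event and unit-cost tables from CSV, enforcing the
#' documented schemas: missing required columns or duplicate patient ids
#' abort; malformed event rows (unparseable date, unknown care type,
#' negative cost) are collected into a rejects table with reasons rather
#' than aborting.
#'
#' @param patient_file,event_file,unit_cost_file CSV paths. The unit-cost
#'   file has columns `item` (`gp_consultation` or a BNF chapter) and
#'   `cost`.
#' @return List with `patients`, `events`, `unit_costs` (a
#'   [unit_cost_table()]) and `rejects` (tibble `row`, `reason`).
#' @export
read_inputs <- function(patient_file, event_file, unit_cost_file = NULL) {
  patients <- suppressWarnings(readr::read_csv(patient_file,
    col_types = patient_col_types(), progress = FALSE
  ))
  req_pat <- c(
    "patient_id", "age", "sex", "region",
    "registration_start", "registration_end"
  )
  miss <- setdiff(req_pat, names(patients))
  if (length(miss)) {
    stop(sprintf("patient table missing columns: %s", paste(miss, collapse = ", ")),
      call. = FALSE
    )
  }
  dup <- patients$patient_id[duplicated(patients$patient_id)]
  if (length(dup)) {
    stop(sprintf("duplicate patient_id: %s", paste(unique(dup), collapse = ", ")),
      call. = FALSE
    )
  }

  events <- suppressWarnings(readr::read_csv(event_file,
    col_types = event_col_types(), progress = FALSE
  ))
  req_ev <- c("patient_id", "date", "care_type")
  miss <- setdiff(req_ev, names(events))
  if (length(miss)) {
    stop(sprintf("event table missing columns: %s", paste(miss, collapse = ", ")),
      call. = FALSE
    )
  }
  parsed_date <- as.Date(suppressWarnings(
    readr::parse_date(events$date, format = "%Y-%m-%d")
  ))
  reason <- rep(NA_character_, nrow(events))
  reason[is.na(parsed_date)] <- "bad date"
  reason[is.na(reason) & !(events$care_type %in% care_types())] <- "unknown care_type"
  if ("cost" %in% names(events)) {
    reason[is.na(reason) & !is.na(events$cost) & events$cost < 0] <- "negative cost"
  }
  rejects <- tibble::tibble(row = which(!is.na(reason)), reason = reason[!is.na(reason)])
  events$date <- parsed_date
  events <- events[is.na(reason), , drop = FALSE]
  if (!"cost" %in% names(events)) events$cost <- NA_real_
  if (!"discharge_date" %in% names(events)) events$discharge_date <- as.Date(NA)

  unit_costs <- unit_cost_table()
  if (!is.null(unit_cost_file)) {
    uc <- readr::read_csv(unit_cost_file,
      col_types = readr::cols(
        item = readr::col_character(),
        cost = readr::col_double()
      ), progress = FALSE
    )
    if (!all(c("item", "cost") %in% names(uc))) {
      stop("unit-cost table must have columns 'item' and 'cost'", call. = FALSE)
    }
    gp <- uc$cost[uc$item == "gp_consultation"]
    chapters <- uc[uc$item != "gp_consultation", , drop = FALSE]
    unit_costs <- unit_cost_table(
      gp_consultation_cost = if (length(gp)) gp[1] else 41,
      bnf_chapter_costs = stats::setNames(chapters$cost, chapters$item)
    )
  }
  list(patients = patients, events = events, unit_costs = unit_costs, rejects = rejects)
}

#' Write the standard pipeline tables
#'
#' Thin wrappers over [readr::write_csv()] so every intermediate uses one
#' stable, documented schema. Currency columns are written at full
#' precision.
#'
#' @param x Table to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(x, path, na = "")
  invisible(path)
}

#' @rdname write_table
#' @param unit_costs A [unit_cost_table()].
#' @export
write_unit_costs <- function(unit_costs, path) {
  write_table(tibble::tibble(
    item = c("gp_consultation", names(unit_costs$bnf_chapter_costs)),
    cost = c(unit_costs$gp_consultation_cost, unname(unit_costs$bnf_chapter_costs))
  ), path)
}
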