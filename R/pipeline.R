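# End-to-end orchestration: simulate (or read) -> eligibility -> matching ->
# outcomes -> two-part fits -> predictions -> DID -> descriptives ->
# sensitivity suite, writing every intermediate plus a run log.

#' Pipeline configuration
#'
#' Collects the study constants and run options. Defaults follow the study
#' design: study start 1 November 2020, administrative end of follow-up
#' 31 January 2023, 12-month outcome window, 1:5 exact matching on age,
#' sex and region, historical window March 2019 - March 2020.
#'
#' @param simulate Generate a synthetic cohort (`TRUE`) or read input files.
#' @param sim_params A [simulation_params()] (when `simulate = TRUE`).
#' @param patient_file,event_file,unit_cost_file Input CSV paths (when
#'   `simulate = FALSE`).
#' @param output_dir Directory for all written artifacts.
#' @param study_start,admin_end,min_registration_days Eligibility constants.
#' @param match_ratio,match_vars Matching constants.
#' @param window_days Outcome window length in days.
#' @param covariates Adjustment set for all models.
#' @param dispersion_threshold Deviance/df ratio above which the count part
#'   is negative binomial.
#' @param bootstrap_reps Cluster-bootstrap replicates for predicted-mean and
#'   DID intervals; values below 100 mean point estimates only.
#' @param components Also fit the five per-care-type utilisation outcomes.
#' @param do_did,do_sensitivity Toggle the historical comparison and the
#'   sensitivity suite.
#' @param restrictions Restriction rules to run within the sensitivity
#'   suite (subset of the [apply_restriction()] rules).
#' @param trend_bins Pre-period bins for the common-trend check.
#' @param seed Master seed for matching, event generation and bootstrap.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE,
                            sim_params = simulation_params(),
                            patient_file = NULL, event_file = NULL,
                            unit_cost_file = NULL,
                            output_dir = file.path(tempdir(), "hurdlecohort_run"),
                            study_start = as.Date("2020-11-01"),
                            admin_end = as.Date("2023-01-31"),
                            min_registration_days = 90,
                            match_ratio = 5,
                            match_vars = c("age", "sex", "region"),
                            window_days = 365,
                            covariates = c(
                              "age_cat", "sex", "ethnicity", "imd_quintile",
                              "region", "asthma", "mental_health",
                              "n_comorbidities", "prior_covid_hospitalisation",
                              "n_vaccine_doses"
                            ),
                            dispersion_threshold = 1,
                            bootstrap_reps = 0,
                            components = FALSE,
                            do_did = TRUE,
                            do_sensitivity = TRUE,
                            restrictions = "positive_test_before_index",
                            trend_bins = 4,
                            seed = 20201101L) {
  study_start <- assert_date(study_start)
  admin_end <- assert_date(admin_end)
  if (admin_end <= study_start) stop("admin_end must follow study_start", call. = FALSE)
  if (match_ratio < 1) stop("match_ratio must be >= 1", call. = FALSE)
  structure(as.list(environment()), class = "pipeline_config")
}

# simulate the full cohort scaffold: population, matching, follow-up and
# event streams for both observation periods
#' Simulate a complete matched cohort with event streams
#'
#' Runs the generator through eligibility, matching and follow-up, then
#' draws contemporary event streams over each member's censored follow-up
#' window and historical streams over the fixed pre-pandemic window for
#' members meeting the historical registration requirement.
#'
#' @param params A [simulation_params()].
#' @param config A [pipeline_config()] (supplies study constants).
#' @return List: `patients`, `truth`, `eligible`, `exclusions`, `members`,
#'   `follow_ups`, `events`, `unit_costs`.
#' @export
simulate_cohort <- function(params = simulation_params(),
                            config = pipeline_config()) {
  pop <- generate_population(params)
  elig <- apply_eligibility(pop$patients,
    study_start = config$study_start,
    min_registration_days = config$min_registration_days
  )
  members <- match_exposed(elig$eligible,
    ratio = config$match_ratio,
    match_vars = config$match_vars, seed = config$seed + 7L
  )
  fu <- compute_follow_up(members, pop$patients,
    window_days = config$window_days, admin_end = config$admin_end
  )
  # one envelope window per patient (a person can hold a comparator window
  # before their own diagnosis and an exposed window after it)
  cw <- fu[fu$follow_up_days > 0, c("patient_id", "start", "end")] |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end))
  ev_cont <- generate_event_stream(pop$patients, cw, params,
    period = "contemporary", seed = params$seed + 101L
  )
  hw <- historical_window()
  pat <- dplyr::left_join(
    members[!duplicated(members$patient_id), c("patient_id", "index_date")],
    pop$patients, by = "patient_id"
  )
  hist_ok <- pat$registration_start <= hw[["start"]] &
    pat$registration_end >= pat$index_date
  hwin <- tibble::tibble(
    patient_id = pat$patient_id[hist_ok],
    start = hw[["start"]],
    end = pmin(
      hw[["end"]],
      pat$registration_end[hist_ok] + 1,
      dplyr::coalesce(pat$death_date[hist_ok], as.Date("9999-12-31"))
    )
  )
  hwin <- hwin[as.numeric(hwin$end - hwin$start) > 0, ]
  ev_hist <- generate_event_stream(pop$patients, hwin, params,
    period = "historical", seed = params$seed + 202L
  )
  list(
    patients = pop$patients, truth = pop$truth,
    eligible = elig$eligible, exclusions = elig$exclusions,
    members = members, follow_ups = fu,
    events = dplyr::bind_rows(ev_hist, ev_cont),
    unit_costs = unit_cost_table(41, params$bnf_chapter_costs)
  )
}

#' Run the full analysis pipeline
#'
#' Executes eligibility, matching, outcome construction, the two-part fits
#' for utilisation and cost (total and, optionally, per care type),
#' marginally standardised predictions, the historical
#' difference-in-difference comparison with common-trend check, Table-1
#' descriptives and the sensitivity suite, writing every intermediate table
#' and a run log under `config$output_dir`. Re-running with an identical
#' configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list bundle with all intermediates and results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- c(
    sprintf("hurdlecohort %s | R %s", utils::packageVersion("hurdlecohort"),
      getRversion()),
    sprintf("seed: %d", config$seed),
    "config:",
    utils::capture.output(utils::str(unclass(config), give.attr = FALSE))
  )
  writeLines(log_lines, log_path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cat(sprintf("FAILED at stage '%s': %s\n", name, conditionMessage(e)),
        file = log_path, append = TRUE
      )
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  bundle <- list(config = config)

  if (config$simulate) {
    sim <- stage("simulate", {
      params <- config$sim_params
      params$seed <- config$seed
      simulate_cohort(params, config)
    })
    bundle <- c(bundle, sim)
    write_table(sim$patients, file.path(out_dir, "patients.csv"))
    write_table(sim$events, file.path(out_dir, "events.csv"))
    write_table(sim$truth$patients, file.path(out_dir, "ground_truth.csv"))
    write_unit_costs(sim$unit_costs, file.path(out_dir, "unit_costs.csv"))
  } else {
    inp <- stage("read_inputs", {
      read_inputs(config$patient_file, config$event_file, config$unit_cost_file)
    })
    elig <- stage("eligibility", {
      apply_eligibility(inp$patients,
        study_start = config$study_start,
        min_registration_days = config$min_registration_days
      )
    })
    members <- stage("matching", {
      match_exposed(elig$eligible,
        ratio = config$match_ratio,
        match_vars = config$match_vars, seed = config$seed + 7L
      )
    })
    fu <- stage("follow_up", {
      compute_follow_up(members, inp$patients,
        window_days = config$window_days, admin_end = config$admin_end
      )
    })
    bundle <- c(bundle, list(
      patients = inp$patients, events = inp$events,
      unit_costs = inp$unit_costs, rejects = inp$rejects,
      eligible = elig$eligible, exclusions = elig$exclusions,
      members = members, follow_ups = fu
    ))
    if (nrow(inp$rejects)) write_table(inp$rejects, file.path(out_dir, "rejects.csv"))
  }
  write_table(bundle$exclusions, file.path(out_dir, "exclusions.csv"))
  write_table(bundle$members, file.path(out_dir, "matched_sets.csv"))
  write_table(bundle$follow_ups, file.path(out_dir, "follow_up.csv"))

  rows <- stage("outcomes", {
    build_analysis_rows(bundle$members, bundle$follow_ups, bundle$events,
      bundle$patients, bundle$unit_costs,
      period = "contemporary"
    )
  })
  bundle$rows <- rows
  write_table(rows, file.path(out_dir, "analysis_rows.csv"))

  tab1 <- stage("descriptives", {
    mem1 <- bundle$members[!duplicated(bundle$members$patient_id), ]
    pat1 <- dplyr::inner_join(
      bundle$patients, mem1[, c("patient_id", "group")], by = "patient_id"
    )
    table_one(pat1, pat1$group)
  })
  bundle$table_one <- tab1
  write_table(tab1, file.path(out_dir, "table_one.csv"))

  outcomes <- "total_visits"
  if (config$components) {
    outcomes <- c(outcomes, "n_gp", "n_prescription", "n_ae", "n_admission", "n_outpatient")
  }
  outcomes <- c(outcomes, "total_cost")
  fits <- list()
  est <- list()
  preds <- list()
  for (oc in outcomes) {
    sp <- model_spec(
      outcome = oc, covariates = config$covariates,
      dispersion_threshold = config$dispersion_threshold
    )
    fit <- stage(paste0("fit_", oc), fit_two_part(rows, sp))
    fits[[oc]] <- fit
    est[[oc]] <- dplyr::mutate(part_estimates(fit),
      outcome = oc, family = fit$family_used, .before = 1
    )
    nb <- if (oc %in% c("total_visits", "total_cost")) config$bootstrap_reps else 0
    pm <- stage(paste0("predict_", oc), {
      point <- tibble::tibble(
        group = c("exposed", "comparator"),
        predicted_mean = c(
          predict_average(fit, rows, "exposed"),
          predict_average(fit, rows, "comparator")
        ),
        ci_low = NA_real_, ci_high = NA_real_, n_bootstrap = nb
      )
      if (nb >= 100) {
        point <- predicted_means(rows, sp, n_reps = nb, seed = config$seed + 11L)
      }
      point
    })
    preds[[oc]] <- dplyr::mutate(pm, outcome = oc, .before = 1)
  }
  bundle$fits <- fits
  bundle$estimates <- dplyr::bind_rows(est)
  bundle$predictions <- dplyr::bind_rows(preds)
  write_table(bundle$estimates, file.path(out_dir, "estimates.csv"))
  write_table(bundle$predictions, file.path(out_dir, "predictions.csv"))

  if (config$do_did) {
    did_rows <- stage("did_rows", {
      build_did_rows(
        bundle$members, bundle$follow_ups, bundle$events,
        bundle$patients, bundle$unit_costs
      )
    })
    did <- stage("did_fit", {
      fit_did(did_rows,
        model_spec(outcome = "total_visits", covariates = config$covariates),
        n_boot = if (config$bootstrap_reps >= 100) config$bootstrap_reps else 0,
        seed = config$seed + 13L
      )
    })
    trend <- stage("common_trend", {
      check_common_trend(bundle$members, bundle$events, bundle$patients,
        bins = config$trend_bins,
        plot_file = file.path(out_dir, "pre_trend.png")
      )
    })
    bundle$did_rows <- did_rows
    bundle$did <- did
    bundle$trend <- trend
    write_table(tibble::tibble(
      cell = names(did$cell_means), predicted_mean = unname(did$cell_means)
    ), file.path(out_dir, "did_cell_means.csv"))
    write_table(tibble::tibble(
      did_estimate = did$did_estimate, ci_low = did$ci_low,
      ci_high = did$ci_high,
      interaction_part1_logit = did$interaction[["part1_logit"]],
      interaction_part2_log = did$interaction[["part2_log"]]
    ), file.path(out_dir, "did_result.csv"))
    write_table(trend, file.path(out_dir, "pre_trend.csv"))
  }

  if (config$do_sensitivity) {
    sens <- stage("sensitivity", {
      imputed_events <- impute_missing_costs(bundle$events)
      rows_imp <- build_analysis_rows(bundle$members, bundle$follow_ups,
        imputed_events, bundle$patients, bundle$unit_costs,
        period = "contemporary"
      )
      cost_sp <- model_spec(outcome = "total_cost", covariates = config$covariates)
      fit_imp <- fit_two_part(rows_imp, cost_sp)
      strat <- stratified_analysis(
        rows,
        model_spec(outcome = "total_visits", covariates = config$covariates)
      )
      restr <- list()
      for (rule in config$restrictions) {
        rs <- apply_restriction(bundle$patients, bundle$events, rule,
          index_dates = bundle$members
        )
        rrows <- if (rule == "drop_first_gp_event") {
          build_analysis_rows(bundle$members, bundle$follow_ups, rs$events,
            bundle$patients, bundle$unit_costs,
            period = "contemporary"
          )
        } else {
          rows[rows$patient_id %in% rs$patients$patient_id, , drop = FALSE]
        }
        rfit <- fit_two_part(
          rrows, model_spec(outcome = "total_visits", covariates = config$covariates)
        )
        restr[[rule]] <- dplyr::mutate(effect_estimates(rfit),
          rule = rule, n_rows = nrow(rrows), .before = 1
        )
      }
      list(
        imputed_cost_fit = fit_imp,
        imputed_cost_effects = effect_estimates(fit_imp),
        stratified = strat,
        restrictions = dplyr::bind_rows(restr)
      )
    })
    bundle$sensitivity <- sens
    write_table(sens$stratified, file.path(out_dir, "stratified_estimates.csv"))
    if (nrow(sens$restrictions)) {
      write_table(sens$restrictions, file.path(out_dir, "restriction_estimates.csv"))
    }
  }

  cat("completed\n", file = log_path, append = TRUE)
  invisible(bundle)
}
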