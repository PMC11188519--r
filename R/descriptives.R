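# Table-1 descriptives, missing-cost imputation, stratified analyses with
# interaction tests, and cohort restrictions.

default_table_factors <- function() {
  c(
    "sex", "age_cat", "ethnicity", "bmi_category", "imd_quintile", "region",
    "asthma", "mental_health", "n_comorbidities",
    "prior_covid_hospitalisation", "n_vaccine_doses",
    "positive_test_before_index"
  )
}

#' Descriptive cohort table with group comparisons
#'
#' Counts and column percentages per factor level by exposure group, with
#' chi-square tests (no continuity correction) for categorical factors and
#' a Welch t-test for age. Percentages use the group total among
#' non-missing values of that factor as denominator; missing values are
#' tabulated as separate `"(missing)"` rows with no percentage and are
#' excluded from the tests.
#'
#' @param patients Patient tibble.
#' @param group Character vector aligned with `patients` rows:
#'   `"exposed"`/`"comparator"`.
#' @param factors Factor columns to tabulate (default the standard
#'   demographic/comorbidity set; `age_cat` is derived from `age`).
#' @param pooled_t Use the pooled-variance t-test instead of Welch.
#' @return Tibble: `factor`, `level`, per-group `n` and `pct`, `mean`/`sd`
#'   columns for continuous factors, `p_value`, `test`.
#' @export
table_one <- function(patients, group, factors = default_table_factors(),
                      pooled_t = FALSE) {
  stopifnot(length(group) == nrow(patients))
  if (!"age_cat" %in% names(patients) && "age" %in% names(patients)) {
    patients$age_cat <- as.character(age_category(patients$age))
  }
  is_exp <- group == "exposed"
  out <- list()

  if ("age" %in% names(patients)) {
    a_e <- patients$age[is_exp]
    a_c <- patients$age[!is_exp]
    p <- tryCatch(
      stats::t.test(a_e, a_c, var.equal = pooled_t)$p.value,
      error = function(e) NA_real_
    )
    out[[1]] <- tibble::tibble(
      factor = "age", level = "Mean (SD)",
      n_exposed = sum(is_exp), pct_exposed = NA_real_,
      n_comparator = sum(!is_exp), pct_comparator = NA_real_,
      mean_exposed = mean(a_e), sd_exposed = stats::sd(a_e),
      mean_comparator = mean(a_c), sd_comparator = stats::sd(a_c),
      p_value = p, test = if (pooled_t) "t-test (pooled)" else "t-test (Welch)"
    )
  }
  for (f in intersect(factors, names(patients))) {
    x <- patients[[f]]
    if (is.logical(x)) x <- ifelse(x, "yes", "no")
    x <- as.character(x)
    obs <- !is.na(x)
    lev <- sort(unique(x[obs]))
    tab <- table(factor(x[obs], levels = lev), factor(is_exp[obs],
      levels = c(TRUE, FALSE)
    ))
    p <- if (length(lev) < 2 || any(colSums(tab) == 0)) {
      NA_real_
    } else {
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }
    den_e <- sum(tab[, 1])
    den_c <- sum(tab[, 2])
    rows <- tibble::tibble(
      factor = f, level = lev,
      n_exposed = as.integer(tab[, 1]),
      pct_exposed = as.numeric(round(100 * tab[, 1] / den_e, 1)),
      n_comparator = as.integer(tab[, 2]),
      pct_comparator = as.numeric(round(100 * tab[, 2] / den_c, 1)),
      mean_exposed = NA_real_, sd_exposed = NA_real_,
      mean_comparator = NA_real_, sd_comparator = NA_real_,
      p_value = p, test = "chi-square"
    )
    if (any(!obs)) {
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        factor = f, level = "(missing)",
        n_exposed = sum(!obs & is_exp), pct_exposed = NA_real_,
        n_comparator = sum(!obs & !is_exp), pct_comparator = NA_real_,
        mean_exposed = NA_real_, sd_exposed = NA_real_,
        mean_comparator = NA_real_, sd_comparator = NA_real_,
        p_value = NA_real_, test = "chi-square"
      ))
    }
    out[[length(out) + 1]] <- rows
  }
  dplyr::bind_rows(out)
}

#' Recompute column percentages from stored counts
#'
#' Given per-level counts by group, recomputes the column percentages to
#' one decimal place, with the within-factor group total (i.e. the
#' non-missing total) as denominator. Used to verify that a printed
#' descriptive table is internally consistent.
#'
#' @param counts Tibble with `factor`, `level`, `n_exposed`,
#'   `n_comparator`.
#' @return The input with `pct_exposed` and `pct_comparator` columns.
#' @export
recompute_percentages <- function(counts) {
  counts |>
    dplyr::group_by(.data$factor) |>
    dplyr::mutate(
      pct_exposed = round(100 * .data$n_exposed / sum(.data$n_exposed), 1),
      pct_comparator = round(100 * .data$n_comparator / sum(.data$n_comparator), 1)
    ) |>
    dplyr::ungroup()
}

#' Impute missing secondary-care costs
#'
#' Replaces each missing A&E, admission or outpatient event cost with the
#' care-type-specific mean of the observed per-event costs. GP and
#' prescription events are never touched (they are unit-costed). Errors if
#' a care type that needs imputation has no observed costs at all.
#'
#' @param events Event tibble.
#' @return The completed event tibble; attribute `"n_imputed"` counts
#'   imputations per care type.
#' @export
impute_missing_costs <- function(events) {
  n_imputed <- integer(0)
  for (tp in c("ae", "admission", "outpatient")) {
    sel <- events$care_type == tp
    miss <- sel & is.na(events$cost)
    if (!any(miss)) next
    obs <- events$cost[sel & !is.na(events$cost)]
    if (length(obs) == 0) {
      stop(sprintf("all '%s' costs are missing; cannot impute", tp), call. = FALSE)
    }
    events$cost[miss] <- mean(obs)
    n_imputed[tp] <- sum(miss)
  }
  attr(events, "n_imputed") <- n_imputed
  events
}

#' Stratified two-part analysis with interaction likelihood-ratio tests
#'
#' For each stratifying variable, refits the two-part model with a
#' `group x stratum` interaction, derives stratum-specific odds ratios and
#' rate (or cost) ratios as linear combinations of coefficients, and tests
#' the interaction against the main-effects model with a likelihood-ratio
#' test per part (df = levels - 1).
#'
#' @param rows AnalysisRow tibble.
#' @param spec A [model_spec()]; each stratifier must be among its
#'   covariates.
#' @param stratify_by Stratifying variables (default sex, age band, prior
#'   COVID-19 hospitalisation).
#' @return Tibble with one row per variable and stratum: `or`, `ratio` and
#'   intervals, plus `lrt_stat_part1/2`, `lrt_df`, `lrt_p_part1/2`.
#' @export
stratified_analysis <- function(rows, spec = model_spec(),
                                stratify_by = c(
                                  "sex", "age_cat",
                                  "prior_covid_hospitalisation"
                                )) {
  missing_strat <- setdiff(stratify_by, spec$covariates)
  if (length(missing_strat)) {
    stop(sprintf(
      "stratifier(s) not among fitted covariates: %s",
      paste(missing_strat, collapse = ", ")
    ), call. = FALSE)
  }
  main <- fit_two_part(rows, spec)
  out <- list()
  for (v in stratify_by) {
    mf <- prepare_model_frame(rows, spec)
    cell <- table(mf$group, mf[[v]])
    if (any(cell == 0)) {
      empty <- which(cell == 0, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "empty group x stratum cell: %s x %s = %s",
        rownames(cell)[empty[1]], v, colnames(cell)[empty[2]]
      ), call. = FALSE)
    }
    # refit the main-effects second part under the interaction family so the
    # LRT compares nested models of the same family
    ifit <- fit_two_part(rows, spec, interaction = v)
    main2 <- if (!spec$is_cost && ifit$family_used != main$family_used) {
      fit_two_part(rows, model_spec(
        outcome = spec$outcome, covariates = spec$covariates,
        family = ifit$family_used,
        dispersion_threshold = spec$dispersion_threshold,
        missing_as_category = spec$missing_as_category
      ))
    } else {
      main
    }
    levs <- levels(mf[[v]])
    df <- length(levs) - 1
    lrt <- function(part_i, part_m) {
      stat <- max(0, 2 * (part_i$loglik - part_m$loglik))
      c(stat = stat, p = stats::pchisq(stat, df, lower.tail = FALSE))
    }
    l1 <- lrt(ifit$part1, main2$part1)
    l2 <- lrt(ifit$part2, main2$part2)

    contrast <- function(part, lev) {
      terms <- "groupexposed"
      if (lev != levs[1]) terms <- c(terms, paste0("groupexposed:", v, lev))
      co <- part$coefficients
      keep <- intersect(terms, names(co))
      est <- sum(co[keep])
      w <- as.numeric(names(co) %in% keep)
      se <- sqrt(drop(t(w) %*% part$vcov %*% w))
      c(est = est, se = se)
    }
    for (lev in levs) {
      c1 <- contrast(ifit$part1, lev)
      c2 <- contrast(ifit$part2, lev)
      out[[length(out) + 1]] <- tibble::tibble(
        variable = v, stratum = lev,
        or = exp(c1[["est"]]),
        or_low = exp(c1[["est"]] - 1.96 * c1[["se"]]),
        or_high = exp(c1[["est"]] + 1.96 * c1[["se"]]),
        ratio = exp(c2[["est"]]),
        ratio_low = exp(c2[["est"]] - 1.96 * c2[["se"]]),
        ratio_high = exp(c2[["est"]] + 1.96 * c2[["se"]]),
        lrt_stat_part1 = l1[["stat"]], lrt_p_part1 = l1[["p"]],
        lrt_stat_part2 = l2[["stat"]], lrt_p_part2 = l2[["p"]],
        lrt_df = df
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Apply a sensitivity-analysis cohort restriction
#'
#' * `prior_gp_consult_within_1y`: keep patients with at least one GP event
#'   in the year before the study start (1 Nov 2019 window start shifted:
#'   `[2019-11-01, 2020-11-01)`).
#' * `positive_test_before_index`: keep patients with a positive SARS-CoV-2
#'   test before their index date.
#' * `drop_first_gp_event`: remove each person's earliest post-index GP
#'   event from the event stream before counting (requires `index_dates`).
#'
#' @param patients Patient tibble.
#' @param events Event tibble.
#' @param rule One of the three rule names.
#' @param index_dates Tibble `patient_id`, `index_date` (needed for
#'   `drop_first_gp_event`).
#' @return List with restricted `patients`, `events` and `n_dropped`.
#' @export
apply_restriction <- function(patients, events,
                              rule = c(
                                "prior_gp_consult_within_1y",
                                "positive_test_before_index",
                                "drop_first_gp_event"
                              ),
                              index_dates = NULL) {
  valid <- c(
    "prior_gp_consult_within_1y", "positive_test_before_index",
    "drop_first_gp_event"
  )
  if (length(rule) != 1L || !rule %in% valid) {
    stop(sprintf("unknown rule; valid rules: %s", paste(valid, collapse = ", ")),
      call. = FALSE
    )
  }
  if (rule == "prior_gp_consult_within_1y") {
    w0 <- as.Date("2019-11-01")
    w1 <- as.Date("2020-11-01")
    has_gp <- unique(events$patient_id[
      events$care_type == "gp" & !is.na(events$date) &
        events$date >= w0 & events$date < w1
    ])
    keep <- patients$patient_id %in% has_gp
    return(list(
      patients = patients[keep, , drop = FALSE], events = events,
      n_dropped = sum(!keep)
    ))
  }
  if (rule == "positive_test_before_index") {
    keep <- !is.na(patients$positive_test_before_index) &
      patients$positive_test_before_index
    return(list(
      patients = patients[keep, , drop = FALSE], events = events,
      n_dropped = sum(!keep)
    ))
  }
  # drop_first_gp_event
  if (is.null(index_dates)) {
    stop("drop_first_gp_event requires index_dates (patient_id, index_date)",
      call. = FALSE
    )
  }
  ev <- dplyr::left_join(
    dplyr::mutate(events, .row = dplyr::row_number()),
    index_dates[, c("patient_id", "index_date")],
    by = "patient_id"
  )
  post_gp <- ev[ev$care_type == "gp" & !is.na(ev$index_date) &
    !is.na(ev$date) & ev$date >= ev$index_date, , drop = FALSE]
  first <- post_gp |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_min(.data$date, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  keep_rows <- setdiff(seq_len(nrow(events)), first$.row)
  list(
    patients = patients, events = events[keep_rows, , drop = FALSE],
    n_dropped = nrow(first)
  )
}
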