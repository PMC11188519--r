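# Historical comparison: two-part difference-in-differences on the
# absolute predicted scale, plus the common-trend check.

#' Build the stacked person-period rows for the DID analysis
#'
#' Two rows per person: a historical row over the fixed March 2019 - March
#' 2020 window and a contemporary row over the censored post-index
#' follow-up, restricted to set members registered from the start of the
#' historical window through their index date. Persons with only one usable
#' period are excluded (count in attribute `"excluded_single_period"`).
#'
#' @param members Long matched-set tibble.
#' @param follow_ups Output of [compute_follow_up()].
#' @param events Event tibble covering both periods.
#' @param patients Patient tibble.
#' @param unit_costs A [unit_cost_table()].
#' @return Stacked AnalysisRow tibble with a `period` column.
#' @export
build_did_rows <- function(members, follow_ups, events, patients,
                           unit_costs = unit_cost_table()) {
  hist <- build_analysis_rows(members, follow_ups, events, patients,
    unit_costs,
    period = "historical"
  )
  cont <- build_analysis_rows(members, follow_ups, events, patients,
    unit_costs,
    period = "contemporary"
  )
  key <- function(d) paste(d$patient_id, d$set_id)
  both <- intersect(key(hist), key(cont))
  out <- dplyr::bind_rows(
    hist[key(hist) %in% both, , drop = FALSE],
    cont[key(cont) %in% both, , drop = FALSE]
  )
  n_single <- (nrow(hist) + nrow(cont) - nrow(out)) -
    0L # rows lost to single-period persons
  attr(out, "excluded_single_period") <- n_single
  out
}

#' Fit the two-part difference-in-difference model
#'
#' Fits both parts with `group`, `period` and their interaction (plus the
#' covariates of the spec), computes the four marginally standardised
#' predicted means (each group by each period, at one person-year), the
#' within-group before/after differences, and the DID contrast
#' `(exposed post - exposed pre) - (comparator post - comparator pre)` on
#' the absolute scale. Optionally attaches a percentile cluster-bootstrap
#' interval for the contrast.
#'
#' @param rows Stacked rows from [build_did_rows()].
#' @param spec A [model_spec()] (visit outcomes).
#' @param n_boot Bootstrap replicates for the DID interval (0 = none).
#' @param seed Bootstrap seed.
#' @return A `did_result` list: `cell_means`, `within_diffs`,
#'   `did_estimate`, `ci_low`/`ci_high`, `interaction` (both parts' group
#'   x period coefficients on their linear scales), `fit`.
#' @export
fit_did <- function(rows, spec = model_spec(), n_boot = 0, seed = 1L) {
  if (length(unique(rows$period)) < 2) {
    stop("both periods must be present in the DID rows", call. = FALSE)
  }
  cells_of <- function(r, fit) {
    c(
      exposed_historical = predict_average(fit, r, "exposed", "historical"),
      exposed_contemporary = predict_average(fit, r, "exposed", "contemporary"),
      comparator_historical = predict_average(fit, r, "comparator", "historical"),
      comparator_contemporary = predict_average(fit, r, "comparator", "contemporary")
    )
  }
  did_of <- function(cells) {
    (cells[["exposed_contemporary"]] - cells[["exposed_historical"]]) -
      (cells[["comparator_contemporary"]] - cells[["comparator_historical"]])
  }
  fit <- fit_two_part(rows, spec, interaction = "period")
  # standardise over persons, not stacked person-periods
  std_rows <- rows[!duplicated(paste(rows$patient_id, rows$set_id)), , drop = FALSE]
  cells <- cells_of(std_rows, fit)
  did <- did_of(cells)

  ci <- c(NA_real_, NA_real_)
  boot_se <- NA_real_
  if (n_boot > 0) {
    spec_b <- spec
    if (!spec$is_cost) spec_b$family <- fit$family_used
    bs <- bootstrap_ci(rows, function(r) {
      f <- fit_two_part(r, spec_b, interaction = "period", hessian = FALSE)
      s <- r[!duplicated(paste(r$patient_id, r$set_id)), , drop = FALSE]
      c(did = did_of(cells_of(s, f)))
    }, n_reps = n_boot, seed = seed)
    ci <- c(bs$ci$ci_low, bs$ci$ci_high)
    boot_se <- stats::sd(bs$reps[, 1])
  }
  term <- "groupexposed:periodcontemporary"
  structure(
    list(
      cell_means = cells,
      within_diffs = c(
        exposed = cells[["exposed_contemporary"]] - cells[["exposed_historical"]],
        comparator = cells[["comparator_contemporary"]] - cells[["comparator_historical"]]
      ),
      did_estimate = did,
      ci_low = ci[1], ci_high = ci[2], boot_se = boot_se,
      n_bootstrap = n_boot,
      interaction = c(
        part1_logit = unname(fit$part1$coefficients[term]),
        part2_log = unname(fit$part2$coefficients[term])
      ),
      fit = fit
    ),
    class = "did_result"
  )
}

#' @export
print.did_result <- function(x, ...) {
  cat("Two-part difference-in-difference (visits per person-year)\n")
  print(round(x$cell_means, 2))
  cat(sprintf(
    "DID estimate: %.2f%s\n", x$did_estimate,
    if (!is.na(x$ci_low)) sprintf(" (95%% CI %.2f to %.2f)", x$ci_low, x$ci_high) else ""
  ))
  invisible(x)
}

#' Common-trend check for the DID analysis
#'
#' Splits the pre-period into equal calendar bins and reports, per group
#' and bin, total deduplicated visits, person-time and the visit rate per
#' person-year, together with the exposed-minus-comparator gap per bin.
#' Under the common-trend assumption the gap is stable across bins.
#'
#' @param members Long matched-set tibble (defines the groups).
#' @param events Event tibble.
#' @param patients Patient tibble (for registration intervals).
#' @param bins Number of pre-period bins (>= 2).
#' @param window Date vector `c(start, end)`; defaults to the historical
#'   window.
#' @param plot_file Optional path; if given, a line plot of the per-bin
#'   rates is written there (PNG or any device [ggplot2::ggsave()]
#'   understands).
#' @return Tibble: `bin`, `bin_start`, `bin_end`, `group`, `person_years`,
#'   `visits`, `rate`, `gap` (on exposed rows; NA when a group is absent),
#'   `zero_person_time` flag.
#' @export
check_common_trend <- function(members, events, patients, bins = 4,
                               window = historical_window(),
                               plot_file = NULL) {
  if (bins < 2) stop("need at least 2 pre-period bins", call. = FALSE)
  breaks <- seq(window[["start"]], window[["end"]], length.out = bins + 1)
  mem <- dplyr::left_join(
    members,
    patients[, c("patient_id", "registration_start", "registration_end")],
    by = "patient_id"
  )
  # a person can hold both roles (comparator before their own diagnosis),
  # so the member join is deliberately many-to-many: their pre-period
  # utilisation informs both arms' trends
  ev <- dplyr::inner_join(
    events[, c("patient_id", "date", "care_type", "discharge_date")],
    members[, c("patient_id", "group")],
    by = "patient_id", relationship = "many-to-many"
  )
  out <- list()
  for (b in seq_len(bins)) {
    b0 <- breaks[b]
    b1 <- breaks[b + 1]
    ov_start <- pmax(mem$registration_start, b0)
    ov_end <- pmin(mem$registration_end + 1, b1)
    py <- as_person_years(pmax(as.numeric(ov_end - ov_start), 0))
    for (g in unique(members$group)) {
      sel <- mem$group == g
      evg <- ev[ev$group == g & !is.na(ev$date) &
        ev$date >= b0 & ev$date < b1, , drop = FALSE]
      adm <- evg$care_type == "admission"
      evg <- evg[!adm | (!is.na(evg$discharge_date) &
        evg$discharge_date > evg$date), , drop = FALSE]
      cnt <- nrow(dplyr::distinct(evg[, c("patient_id", "care_type", "date")]))
      pyg <- sum(py[sel])
      out[[length(out) + 1]] <- tibble::tibble(
        bin = b, bin_start = b0, bin_end = b1, group = g,
        person_years = pyg, visits = cnt,
        rate = if (pyg > 0) cnt / pyg else NA_real_,
        zero_person_time = pyg <= 0
      )
    }
  }
  tab <- dplyr::bind_rows(out)
  wide <- tidyr::pivot_wider(tab[, c("bin", "group", "rate")],
    names_from = "group", values_from = "rate"
  )
  gap <- if (all(c("exposed", "comparator") %in% names(wide))) {
    wide$exposed - wide$comparator
  } else {
    rep(NA_real_, nrow(wide))
  }
  tab$gap <- gap[match(tab$bin, wide$bin)]
  if (!is.null(plot_file)) {
    p <- ggplot2::ggplot(
      tab,
      ggplot2::aes(x = .data$bin_start, y = .data$rate, colour = .data$group)
    ) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(
        x = "pre-period bin start", y = "visits per person-year",
        colour = NULL, title = "Pre-period utilisation by group"
      ) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(plot_file, p, width = 7, height = 4, dpi = 150)
  }
  tab
}
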