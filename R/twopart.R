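# Two-part (hurdle) model: binomial first part for any use, zero-truncated
# count part (NB2 or Poisson, chosen by an overdispersion check) for the
# amount of use among users, and a Gamma GLM for costs; covariate-adjusted
# with log person-year offsets in the second part.

#' Specify a two-part model
#'
#' @param outcome Outcome column: a visit count (`total_visits`, `n_gp`,
#'   `n_prescription`, `n_ae`, `n_admission`, `n_outpatient`) or a cost
#'   (`total_cost` or a component cost). Cost outcomes get a Gamma second
#'   part, counts a truncated count part.
#' @param covariates Covariate column names; `group` is always included
#'   first. The default is the full adjustment set: age band, sex,
#'   ethnicity, IMD quintile, region, asthma, mental health, comorbidity
#'   level, prior COVID-19 hospitalisation and vaccine doses.
#' @param family Optional override of the count family (`"poisson"` or
#'   `"negbin"`); `NULL` lets the overdispersion check decide.
#' @param dispersion_threshold Deviance/df ratio above which the negative
#'   binomial is used (default exactly 1).
#' @param missing_as_category Recode missing covariate values to an explicit
#'   `"(missing)"` level (default) instead of complete-case dropping.
#' @return A `model_spec` list.
#' @export
model_spec <- function(outcome = "total_visits",
                       covariates = c(
                         "age_cat", "sex", "ethnicity", "imd_quintile",
                         "region", "asthma", "mental_health",
                         "n_comorbidities", "prior_covid_hospitalisation",
                         "n_vaccine_doses"
                       ),
                       family = NULL,
                       dispersion_threshold = 1,
                       missing_as_category = TRUE) {
  if (!is.null(family)) family <- match.arg(family, c("poisson", "negbin"))
  structure(
    list(
      outcome = outcome,
      covariates = unique(c("group", setdiff(covariates, "group"))),
      family = family,
      dispersion_threshold = dispersion_threshold,
      missing_as_category = missing_as_category,
      is_cost = grepl("cost", outcome)
    ),
    class = "model_spec"
  )
}

# Model frame preparation: factor covariates with stable reference levels,
# missing as an explicit level, group coded comparator -> exposed.
#' @keywords internal
prepare_model_frame <- function(rows, spec, extra = NULL) {
  vars <- unique(c(spec$covariates, extra))
  mf <- rows[, intersect(names(rows), c(
    vars, spec$outcome, "follow_up_days", "set_id", "patient_id", "period"
  )), drop = FALSE]
  missing_vars <- setdiff(vars, names(mf))
  if (length(missing_vars)) {
    stop(sprintf("rows lack covariates: %s", paste(missing_vars, collapse = ", ")),
      call. = FALSE
    )
  }
  for (v in vars) {
    x <- mf[[v]]
    if (v == "group") {
      mf[[v]] <- factor(x, levels = c("comparator", "exposed"))
    } else if (v == "period") {
      mf[[v]] <- factor(x, levels = c("historical", "contemporary"))
    } else if (is.logical(x)) {
      mf[[v]] <- factor(ifelse(x, "yes", "no"), levels = c("no", "yes"))
    } else if (is.character(x) || is.factor(x)) {
      if (spec$missing_as_category) x <- explicit_missing(x)
      mf[[v]] <- factor(x)
    } else if (anyNA(x)) {
      if (spec$missing_as_category) {
        mf[[v]] <- factor(explicit_missing(as.character(x)))
      }
    } else {
      mf[[v]] <- x
    }
  }
  if (!spec$missing_as_category) mf <- mf[stats::complete.cases(mf[, vars]), ]
  mf
}

twopart_formula <- function(spec, response, interaction = NULL) {
  rhs <- spec$covariates
  if (!is.null(interaction)) {
    rhs <- c(sprintf("group * %s", interaction), setdiff(rhs, c("group", interaction)))
  }
  stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

wald_ci <- function(est, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  cbind(ci_low = est - z * se, ci_high = est + z * se)
}

#' Fit the binomial first part
#'
#' Logistic regression of the any-use indicator (`outcome > 0`) on the
#' covariates. Fitted without an offset: the first part models the
#' probability of any use, for which person-time has no logit-scale
#' interpretation.
#'
#' @param rows AnalysisRow tibble.
#' @param spec A [model_spec()].
#' @param interaction Optional covariate interacted with `group`.
#' @return A `twopart_part` object (coefficients, vcov, Wald CIs, logLik).
#' @export
fit_binomial_part <- function(rows, spec, interaction = NULL) {
  mf <- prepare_model_frame(rows, spec, extra = interaction)
  y <- as.numeric(mf[[spec$outcome]] > 0)
  if (length(unique(y)) < 2) {
    stop("outcome indicator is constant (all zero or all non-zero)", call. = FALSE)
  }
  mf$.y <- y
  fit <- suppressWarnings(stats::glm(
    twopart_formula(spec, ".y", interaction),
    family = stats::binomial(), data = mf
  ))
  co <- stats::coef(fit)
  if (any(!is.finite(co)) || any(abs(co[-1]) > 15)) {
    bad <- names(co)[which(!is.finite(co) | abs(co) > 15)]
    bad <- setdiff(bad, "(Intercept)")
    stop(sprintf(
      "perfect separation in the binomial part (covariate: %s)",
      paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  se <- sqrt(diag(stats::vcov(fit)))
  structure(
    list(
      part = "binomial", scale = "logit",
      coefficients = co, vcov = stats::vcov(fit), se = se,
      ci = wald_ci(co, se), loglik = as.numeric(stats::logLik(fit)),
      glm_fit = fit, n = nrow(mf), converged = fit$converged
    ),
    class = "twopart_part"
  )
}

#' Overdispersion check for the count part
#'
#' Fits a Poisson regression with a log person-year offset to the non-zero
#' rows and returns the ratio of residual deviance to residual degrees of
#' freedom. A ratio above the threshold selects the negative binomial
#' family for the truncated count part; otherwise Poisson.
#'
#' @inheritParams fit_binomial_part
#' @param threshold Ratio above which `"negbin"` is chosen (default from
#'   the spec, itself defaulting to 1).
#' @return List with `ratio` and `family`.
#' @export
overdispersion_check <- function(rows, spec, threshold = NULL,
                                 interaction = NULL) {
  threshold <- threshold %||% spec$dispersion_threshold
  mf <- prepare_model_frame(rows, spec, extra = interaction)
  mf <- mf[mf[[spec$outcome]] > 0, , drop = FALSE]
  mf$.off <- log(as_person_years(mf$follow_up_days))
  fml <- twopart_formula(spec, spec$outcome, interaction)
  fit <- suppressWarnings(stats::glm(
    stats::update.formula(fml, . ~ . + offset(.off)),
    family = stats::poisson(), data = mf
  ))
  if (fit$df.residual <= 0) stop("no residual degrees of freedom", call. = FALSE)
  ratio <- fit$deviance / fit$df.residual
  list(ratio = ratio, family = if (ratio > threshold) "negbin" else "poisson")
}

#' Fit the zero-truncated count part
#'
#' Maximum-likelihood zero-truncated NB2 (or Poisson) regression of the
#' positive counts on the covariates with a log person-year offset,
#' via [fit_truncated_glm()]. The exponentiated `group` coefficient is the
#' rate ratio among users.
#'
#' @inheritParams fit_binomial_part
#' @param family `"negbin"` or `"poisson"`, normally from
#'   [overdispersion_check()].
#' @param hessian Compute the observed-information covariance (disable for
#'   bootstrap refits).
#' @return A `twopart_part` object with dispersion `alpha`.
#' @export
fit_truncated_count_part <- function(rows, spec, family = "negbin",
                                     interaction = NULL, hessian = TRUE) {
  mf <- prepare_model_frame(rows, spec, extra = interaction)
  mf <- mf[mf[[spec$outcome]] > 0, , drop = FALSE]
  y <- mf[[spec$outcome]]
  fml <- twopart_formula(spec, spec$outcome, interaction)
  X <- stats::model.matrix(fml, mf)
  off <- log(as_person_years(mf$follow_up_days))
  fit <- fit_truncated_glm(y, X, off, family = family, hessian = hessian)
  se <- sqrt(diag(fit$vcov))
  is_fac <- vapply(mf, is.factor, logical(1))
  structure(
    list(
      part = "truncated_count", scale = "log",
      coefficients = fit$coefficients, vcov = fit$vcov, se = se,
      ci = wald_ci(fit$coefficients, se),
      formula = fml, xlevels = lapply(mf[is_fac], levels),
      alpha = fit$alpha, family_used = fit$family,
      loglik = fit$loglik, loglik_init = fit$loglik_init,
      converged = fit$converged, grad_norm = fit$grad_norm,
      n = nrow(mf)
    ),
    class = "twopart_part"
  )
}

#' Fit the Gamma cost part
#'
#' Gamma GLM with log link and log person-year offset on rows with positive
#' cost; the exponentiated `group` coefficient is the cost ratio.
#'
#' @inheritParams fit_binomial_part
#' @return A `twopart_part` object.
#' @export
fit_gamma_cost_part <- function(rows, spec, interaction = NULL) {
  mf <- prepare_model_frame(rows, spec, extra = interaction)
  y <- mf[[spec$outcome]]
  if (any(y <= 0)) {
    stop("Gamma cost part requires strictly positive costs; filter zero-cost rows upstream",
      call. = FALSE
    )
  }
  mf$.off <- log(as_person_years(mf$follow_up_days))
  fml <- twopart_formula(spec, spec$outcome, interaction)
  fit <- suppressWarnings(stats::glm(
    stats::update.formula(fml, . ~ . + offset(.off)),
    family = stats::Gamma(link = "log"), data = mf
  ))
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(
    list(
      part = "gamma_cost", scale = "log",
      coefficients = co, vcov = stats::vcov(fit), se = se,
      ci = wald_ci(co, se),
      shape = 1 / summary(fit)$dispersion,
      loglik = as.numeric(stats::logLik(fit)),
      glm_fit = fit, n = nrow(mf), converged = fit$converged
    ),
    class = "twopart_part"
  )
}

#' Fit the full two-part model
#'
#' Combines the binomial first part with the appropriate second part:
#' a zero-truncated count regression (family chosen by the overdispersion
#' check unless overridden) for visit outcomes, or a Gamma GLM for cost
#' outcomes (restricted to positive costs).
#'
#' @inheritParams fit_binomial_part
#' @param hessian Compute second-part covariances (disable for bootstrap
#'   refits).
#' @return A `two_part_fit` object with elements `part1`, `part2`,
#'   `family_used`, `dispersion_ratio`, `spec`, `n_rows`, `n_nonzero`.
#' @export
fit_two_part <- function(rows, spec, interaction = NULL, hessian = TRUE) {
  part1 <- fit_binomial_part(rows, spec, interaction)
  if (spec$is_cost) {
    pos <- rows[rows[[spec$outcome]] > 0, , drop = FALSE]
    part2 <- fit_gamma_cost_part(pos, spec, interaction)
    family_used <- "gamma"
    ratio <- NA_real_
  } else if (!is.null(spec$family)) {
    # family fixed by the spec: no need to re-run the deviance check
    family_used <- spec$family
    ratio <- NA_real_
    part2 <- fit_truncated_count_part(rows, spec, family_used, interaction, hessian)
  } else {
    od <- overdispersion_check(rows, spec, interaction = interaction)
    family_used <- od$family
    ratio <- od$ratio
    part2 <- fit_truncated_count_part(rows, spec, family_used, interaction, hessian)
    family_used <- part2$family_used # may fall back to poisson at the boundary
  }
  structure(
    list(
      part1 = part1, part2 = part2,
      family_used = family_used, dispersion_ratio = ratio,
      spec = spec, interaction = interaction,
      n_rows = nrow(rows), n_nonzero = part2$n
    ),
    class = "two_part_fit"
  )
}

#' @export
print.two_part_fit <- function(x, ...) {
  eff <- effect_estimates(x)
  cat(sprintf(
    "Two-part model for '%s' (%d rows, %d non-zero; second part: %s)\n",
    x$spec$outcome, x$n_rows, x$n_nonzero, x$family_used
  ))
  print(as.data.frame(eff), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Headline exposure effects from a two-part fit
#'
#' The exponentiated `group` coefficients: odds ratio of any use from the
#' first part and rate ratio (or cost ratio) among users from the second
#' part, with Wald 95% intervals.
#'
#' @param fit A `two_part_fit`.
#' @return Tibble with `part`, `measure`, `estimate`, `ci_low`, `ci_high`,
#'   `se_log` (standard error on the log/logit scale).
#' @export
effect_estimates <- function(fit) {
  stopifnot(inherits(fit, "two_part_fit"))
  term <- "groupexposed"
  grab <- function(pp, measure) {
    est <- pp$coefficients[[term]]
    se <- pp$se[[term]]
    tibble::tibble(
      part = pp$part, measure = measure,
      estimate = exp(est),
      ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se),
      se_log = se
    )
  }
  dplyr::bind_rows(
    grab(fit$part1, "odds_ratio"),
    grab(fit$part2, if (fit$family_used == "gamma") "cost_ratio" else "rate_ratio")
  )
}

#' Tidy coefficient table for both parts
#'
#' @param fit A `two_part_fit`.
#' @return Tibble: `part`, `term`, `estimate`, `se`, `ci_low`, `ci_high`,
#'   `scale` — the serialisable estimates contract.
#' @export
part_estimates <- function(fit) {
  one <- function(pp) {
    tibble::tibble(
      part = pp$part, term = names(pp$coefficients),
      estimate = unname(pp$coefficients), se = unname(pp$se),
      ci_low = unname(pp$ci[, "ci_low"]), ci_high = unname(pp$ci[, "ci_high"]),
      scale = pp$scale
    )
  }
  dplyr::bind_rows(one(fit$part1), one(fit$part2))
}
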