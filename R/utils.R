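# Shared constants and small helpers.

#' Care types recognised by the pipeline
#'
#' The five categories of healthcare contact tracked by the cohort:
#' GP consultations, prescriptions, A&E attendances, inpatient admissions
#' (stays of more than one day) and outpatient appointments.
#'
#' @return Character vector of the five care-type labels.
#' @export
care_types <- function() {
  c("gp", "prescription", "ae", "admission", "outpatient")
}

# Days used to convert follow-up days to person-years.
DAYS_PER_YEAR <- 365.25

#' @keywords internal
as_person_years <- function(days) as.numeric(days) / DAYS_PER_YEAR

# log(1 - exp(-x)) for x > 0, stable for both small and large x.
# Tiny x (an untruncated mean numerically at 0, reachable mid-optimisation)
# is clamped rather than erroring so the objective stays finite.
log1mexp <- function(x) {
  x <- pmax(x, 1e-300)
  ifelse(x <= log(2), log(-expm1(-x)), log1p(-exp(-x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_date <- function(x, what = deparse(substitute(x))) {
  if (!inherits(x, "Date")) {
    x2 <- suppressWarnings(as.Date(x))
    if (any(is.na(x2) & !is.na(x))) {
      stop(sprintf("'%s' must be a Date or ISO-8601 string", what), call. = FALSE)
    }
    return(x2)
  }
  x
}

# Categorical age bands used in Table 1 and as default model covariates.
#' @keywords internal
age_category <- function(age) {
  cut(age,
    breaks = c(18, 30, 40, 50, 60, 70, Inf),
    labels = c("18-29", "30-39", "40-49", "50-59", "60-69", "70+"),
    right = FALSE
  )
}

# Convert NA in a factor/character covariate to an explicit "(missing)" level.
#' @keywords internal
explicit_missing <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- "(missing)"
  x
}
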