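# Marginal standardisation: absolute-scale predicted means from the two
# parts, and percentile cluster-bootstrap intervals.

# Design matrix for the truncated count part at new data, enforcing the
# factor levels seen at fitting time.
part2_design <- function(part2, newdata) {
  for (v in names(part2$xlevels)) {
    if (!v %in% names(newdata)) next
    x <- as.character(newdata[[v]])
    bad <- setdiff(unique(x[!is.na(x)]), part2$xlevels[[v]])
    if (length(bad) > 0) {
      stop(sprintf(
        "covariate level absent from fit: %s = %s",
        v, paste(bad, collapse = ", ")
      ), call. = FALSE)
    }
    newdata[[v]] <- factor(x, levels = part2$xlevels[[v]])
  }
  stats::model.matrix(part2$formula, newdata)
}

#' Marginally standardised predicted mean on the absolute scale
#'
#' Sets every row's exposure group (and optionally period) counterfactually,
#' multiplies the first-part probability of any use by the second part's
#' conditional mean at a one person-year offset — `mu / (1 - f(0; mu,
#' alpha))` for the truncated count part, the fitted mean for the Gamma cost
#' part — and averages over the rows' covariate distribution. This is the
#' adjusted mean number of visits (or cost in pounds) per person-year.
#'
#' @param fit A `two_part_fit`.
#' @param rows AnalysisRow tibble supplying the standardisation population
#'   (all covariates of the fit must be present).
#' @param group `"exposed"` or `"comparator"`: the counterfactual exposure.
#' @param period Optional counterfactual period (for DID fits).
#' @param p_one If `TRUE`, force the first-part probability to 1 and return
#'   the average conditional mean (decomposition check).
#' @return A single predicted mean.
#' @export
predict_average <- function(fit, rows, group, period = NULL, p_one = FALSE) {
  stopifnot(inherits(fit, "two_part_fit"))
  group <- match.arg(group, c("exposed", "comparator"))
  rows$group <- group
  if (!is.null(period)) rows$period <- match.arg(period, c("historical", "contemporary"))
  mf <- prepare_model_frame(rows, fit$spec, extra = fit$interaction)

  p_hat <- if (p_one) {
    rep(1, nrow(mf))
  } else {
    as.numeric(stats::predict(fit$part1$glm_fit, newdata = mf, type = "response"))
  }
  if (fit$family_used == "gamma") {
    mf$.off <- 0 # one person-year
    cond_mean <- as.numeric(stats::predict(fit$part2$glm_fit,
      newdata = mf, type = "response"
    ))
  } else {
    X <- part2_design(fit$part2, mf)
    mu <- exp(drop(X %*% fit$part2$coefficients)) # offset 0 = 1 person-year
    cond_mean <- truncated_count_mean(mu, fit$part2$alpha)
  }
  mean(p_hat * cond_mean)
}

#' Percentile cluster-bootstrap confidence interval
#'
#' Resamples matched sets (not rows) with replacement, re-runs an arbitrary
#' refit procedure on each resample and returns percentile bounds of the
#' statistic(s) it computes. Deterministic given `seed`.
#'
#' @param rows AnalysisRow tibble with a `set_id` column.
#' @param refit Function taking a resampled rows tibble and returning a
#'   named numeric vector of statistics (e.g. refit both parts and return
#'   predicted means).
#' @param n_reps Number of bootstrap replicates (>= 100 for reported
#'   intervals).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return List with `ci` (tibble: statistic, ci_low, ci_high), `reps`
#'   (replicate-by-statistic matrix) and `n_failed`.
#' @export
bootstrap_ci <- function(rows, refit, n_reps = 1000, seed = 1L, level = 0.95) {
  if (n_reps < 2) stop("n_reps must be at least 2", call. = FALSE)
  set.seed(seed)
  sets <- unique(rows$set_id)
  by_set <- split(seq_len(nrow(rows)), rows$set_id)
  reps <- vector("list", n_reps)
  failed <- 0L
  for (b in seq_len(n_reps)) {
    draw <- sample(as.character(sets), length(sets), replace = TRUE)
    idx_list <- by_set[draw]
    idx <- unlist(idx_list, use.names = FALSE)
    res <- rows[idx, , drop = FALSE]
    # re-key sets so a set drawn twice is two distinct clusters
    res$set_id <- rep.int(seq_along(idx_list), lengths(idx_list))
    reps[[b]] <- tryCatch(refit(res), error = function(e) {
      failed <<- failed + 1L
      NULL
    })
  }
  if (failed / n_reps > 0.05) {
    stop(sprintf("%d of %d bootstrap replicates failed to converge", failed, n_reps),
      call. = FALSE
    )
  }
  mat <- do.call(rbind, reps)
  a <- (1 - level) / 2
  ci <- tibble::tibble(
    statistic = colnames(mat) %||% paste0("stat", seq_len(ncol(mat))),
    ci_low = apply(mat, 2, stats::quantile, probs = a, names = FALSE),
    ci_high = apply(mat, 2, stats::quantile, probs = 1 - a, names = FALSE)
  )
  list(ci = ci, reps = mat, n_failed = failed)
}

#' Predicted means for both groups with optional bootstrap intervals
#'
#' Convenience wrapper: refits the two-part model on each cluster-bootstrap
#' resample and recomputes both groups' standardised predicted means.
#'
#' @param rows AnalysisRow tibble.
#' @param spec A [model_spec()].
#' @param n_reps Bootstrap replicates; below 100 no intervals are reported
#'   (NA bounds).
#' @param seed Bootstrap seed.
#' @return Tibble: `group`, `predicted_mean`, `ci_low`, `ci_high`,
#'   `n_bootstrap`.
#' @export
predicted_means <- function(rows, spec, n_reps = 0, seed = 1L) {
  fit <- fit_two_part(rows, spec)
  point <- c(
    exposed = predict_average(fit, rows, "exposed"),
    comparator = predict_average(fit, rows, "comparator")
  )
  lo <- hi <- c(exposed = NA_real_, comparator = NA_real_)
  if (n_reps >= 100) {
    spec_b <- spec
    if (!spec$is_cost) spec_b$family <- fit$family_used
    bs <- bootstrap_ci(rows, function(r) {
      f <- fit_two_part(r, spec_b, hessian = FALSE)
      c(
        exposed = predict_average(f, r, "exposed"),
        comparator = predict_average(f, r, "comparator")
      )
    }, n_reps = n_reps, seed = seed)
    lo <- stats::setNames(bs$ci$ci_low, bs$ci$statistic)[names(point)]
    hi <- stats::setNames(bs$ci$ci_high, bs$ci$statistic)[names(point)]
  }
  tibble::tibble(
    group = names(point), predicted_mean = unname(point),
    ci_low = unname(lo), ci_high = unname(hi),
    n_bootstrap = n_reps
  )
}
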