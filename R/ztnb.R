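# Zero-truncated count distributions (Poisson and NB2) and their maximum
# likelihood regression fits with log person-time offsets. These are the
# second-part engines of the two-part model; no installed package provides
# truncated count GLMs, so the likelihood, score and optimiser live here.
#
# NB2 parameterisation throughout: mean mu, variance mu + alpha * mu^2,
# i.e. size theta = 1/alpha in stats::dnbinom terms.

#' Log-probability of a zero-truncated count distribution
#'
#' Log of `f(y; mu, alpha) / (1 - f(0; mu, alpha))` where `f` is the NB2
#' probability mass function when `alpha > 0` and Poisson when `alpha = 0`.
#' This is the building block of the truncated second part of the hurdle
#' model: the distribution of the number of healthcare visits among people
#' with at least one visit.
#'
#' @param y Positive integer counts (vector).
#' @param mu Positive mean of the *untruncated* distribution (vector or scalar).
#' @param alpha Non-negative NB2 dispersion; `alpha = 0` gives the truncated
#'   Poisson limit.
#' @return Log-probabilities, numerically stable for `mu` up to ~1e4 and
#'   `y` up to ~1e5.
#' @examples
#' # geometric case (alpha = 1, mu = 1): P(2) = 0.125 / 0.5 = 0.25
#' exp(truncated_count_logpmf(2, mu = 1, alpha = 1))
#' @export
truncated_count_logpmf <- function(y, mu, alpha) {
  if (any(y < 1)) stop("truncated support starts at y = 1", call. = FALSE)
  if (any(y != round(y))) stop("y must be integer-valued", call. = FALSE)
  if (any(mu <= 0)) stop("mu must be positive", call. = FALSE)
  if (length(alpha) != 1L || alpha < 0) {
    stop("alpha must be a single non-negative number", call. = FALSE)
  }
  if (alpha == 0) {
    # -log f(0) = mu
    stats::dpois(y, mu, log = TRUE) - log1mexp(mu)
  } else {
    theta <- 1 / alpha
    # -log f(0) = theta * log(1 + mu/theta) = theta * log1p(alpha * mu)
    nlogf0 <- theta * log1p(alpha * mu)
    if (alpha < 1e-3) {
      # near the Poisson limit dnbinom loses absolute precision in the
      # lgamma difference; use the exact product form
      # log f = y log mu - log y! - (theta + y) log1p(mu/theta)
      #         + sum_{k=0}^{y-1} log1p(k/theta)
      cs <- c(0, cumsum(log1p((seq_len(max(y)) - 1) / theta)))
      logf <- y * log(mu) - lgamma(y + 1) -
        (theta + y) * log1p(mu / theta) + cs[y + 1]
      logf - log1mexp(nlogf0)
    } else {
      stats::dnbinom(y, size = theta, mu = mu, log = TRUE) - log1mexp(nlogf0)
    }
  }
}

#' Probability of a zero count under NB2 / Poisson
#' @keywords internal
count_log_f0 <- function(mu, alpha) {
  if (alpha == 0) -mu else -(1 / alpha) * log1p(alpha * mu)
}

#' Mean of a zero-truncated count distribution
#'
#' `mu / (1 - f(0; mu, alpha))`: the conditional mean number of events among
#' users, given the untruncated mean `mu`.
#'
#' @inheritParams truncated_count_logpmf
#' @return Conditional means (same length as `mu`).
#' @export
truncated_count_mean <- function(mu, alpha) {
  mu / -expm1(count_log_f0(mu, alpha))
}

# Draw from the zero-truncated distribution by inverse CDF restricted to
# (f(0), 1); exact, and vectorised over mu.
#' @keywords internal
rtrunc_count <- function(n, mu, alpha) {
  f0 <- exp(count_log_f0(mu, alpha))
  u <- stats::runif(n, min = f0, max = 1)
  if (alpha == 0) {
    y <- stats::qpois(u, lambda = mu)
  } else {
    y <- stats::qnbinom(u, size = 1 / alpha, mu = mu)
  }
  pmax(y, 1L)
}

# Probability generating function of the (untruncated) count distribution at
# z in [0, 1]; used for closed-form expectations of same-day-deduplicated
# counts in the synthetic-data oracle.
#' @keywords internal
count_pgf <- function(z, mu, alpha) {
  if (alpha == 0) exp(-mu * (1 - z)) else (1 + alpha * mu * (1 - z))^(-1 / alpha)
}

# ---------------------------------------------------------------------------
# Maximum likelihood regression for zero-truncated counts
# ---------------------------------------------------------------------------

# Negative log-likelihood and analytic score for the truncated NB2 regression.
# par = c(beta, log(theta)); eta = X beta + offset; mu = exp(eta).
ztnb_negll <- function(par, y, X, offset) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  theta <- exp(par[p + 1L])
  mu <- exp(drop(X %*% beta) + offset)
  nlogf0 <- theta * log1p(mu / theta)
  ll <- stats::dnbinom(y, size = theta, mu = mu, log = TRUE) - log1mexp(nlogf0)
  -sum(ll)
}

ztnb_score <- function(par, y, X, offset) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  theta <- exp(par[p + 1L])
  mu <- exp(drop(X %*% beta) + offset)
  f0 <- exp(-theta * log1p(mu / theta))
  omf0 <- -expm1(-theta * log1p(mu / theta))
  # d ll / d eta
  deta <- y - mu * (y + theta) / (theta + mu) - theta * mu * f0 / ((theta + mu) * omf0)
  gbeta <- drop(crossprod(X, deta))
  # d ll / d theta
  dlogf0 <- log(theta / (theta + mu)) + mu / (theta + mu)
  dtheta <- digamma(y + theta) - digamma(theta) + log(theta) + 1 -
    log(theta + mu) - (y + theta) / (theta + mu) + f0 * dlogf0 / omf0
  -c(gbeta, sum(dtheta) * theta) # chain rule for log(theta)
}

ztpois_negll <- function(beta, y, X, offset) {
  mu <- exp(drop(X %*% beta) + offset)
  -sum(stats::dpois(y, mu, log = TRUE) - log1mexp(mu))
}

ztpois_score <- function(beta, y, X, offset) {
  mu <- exp(drop(X %*% beta) + offset)
  deta <- y - mu - mu * exp(-mu) / -expm1(-mu)
  -drop(crossprod(X, deta))
}

# Observed information via central differences of the analytic score
# (one score evaluation per perturbed parameter; symmetrised).
num_hessian <- function(gr, par, ..., eps = 1e-6) {
  k <- length(par)
  H <- matrix(0, k, k)
  h <- pmax(abs(par), 1) * eps
  for (i in seq_len(k)) {
    pp <- par
    pp[i] <- pp[i] + h[i]
    pm <- par
    pm[i] <- pm[i] - h[i]
    H[i, ] <- (gr(pp, ...) - gr(pm, ...)) / (2 * h[i])
  }
  (H + t(H)) / 2
}

#' Fit a zero-truncated count regression by maximum likelihood
#'
#' Maximises the zero-truncated NB2 (or Poisson) log-likelihood with a log
#' link and a fixed offset. Initialised from an untruncated Poisson fit
#' (with a moment estimate of the dispersion from its Pearson residuals);
#' the dispersion is estimated jointly on the log scale. Covariance is the
#' inverse observed information at the optimum.
#'
#' @param y Positive integer response.
#' @param X Design matrix (including intercept).
#' @param offset Numeric offset on the log scale (log person-years).
#' @param family `"negbin"` or `"poisson"`.
#' @param grad_tol Convergence tolerance on the score norm (per observation).
#' @param maxit Maximum BFGS iterations.
#' @param hessian Compute the observed-information covariance (disable for
#'   bootstrap refits where only point estimates are needed).
#' @return List with `coefficients`, `alpha`, `vcov` (for the coefficients),
#'   `loglik`, `loglik_init`, `converged`, `family`, `n`, `grad_norm`.
#' @export
fit_truncated_glm <- function(y, X, offset = rep(0, length(y)),
                              family = c("negbin", "poisson"),
                              grad_tol = 1e-8, maxit = 500, hessian = TRUE) {
  family <- match.arg(family)
  if (any(y < 1)) stop("all responses must be >= 1 (truncated support)", call. = FALSE)
  y <- as.numeric(y)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  p <- ncol(X)

  if (family == "negbin") {
    # initialise from an untruncated Poisson fit plus a moment estimate of
    # the NB2 dispersion from its Pearson residuals
    pois0 <- suppressWarnings(
      stats::glm.fit(X, y, offset = offset, family = stats::poisson())
    )
    beta0 <- pois0$coefficients
    mu0 <- pois0$fitted.values
    alpha0 <- sum((y - mu0)^2 - mu0) / sum(mu0^2)
    theta0 <- 1 / min(max(alpha0, 1e-3), 100)
    par0 <- c(beta0, log(theta0))
    ll0 <- -ztnb_negll(par0, y, X, offset)
    opt <- suppressWarnings(stats::optim(par0, ztnb_negll, ztnb_score,
      y = y, X = X, offset = offset,
      method = "BFGS",
      control = list(maxit = maxit, reltol = 1e-14)
    ))
    gn <- sqrt(sum(ztnb_score(opt$par, y, X, offset)^2)) / length(y)
    if (gn > grad_tol) {
      # polish with a second pass from the current point
      opt2 <- suppressWarnings(stats::optim(opt$par, ztnb_negll, ztnb_score,
        y = y, X = X, offset = offset,
        method = "BFGS", control = list(maxit = maxit, reltol = 1e-15)
      ))
      if (opt2$value <= opt$value) opt <- opt2
      gn <- sqrt(sum(ztnb_score(opt$par, y, X, offset)^2)) / length(y)
    }
    if (gn > 1e-4) {
      stop(sprintf(
        "truncated NB fit did not converge (score norm %.2e); trace: value %.6f after %d fn evals",
        gn, opt$value, opt$counts[1]
      ), call. = FALSE)
    }
    theta_hat <- exp(opt$par[p + 1L])
    alpha_hat <- 1 / theta_hat
    if (alpha_hat < 1e-6) {
      warning("dispersion estimate at the Poisson boundary; refitting as truncated Poisson",
        call. = FALSE
      )
      return(fit_truncated_glm(y, X, offset,
        family = "poisson",
        grad_tol = grad_tol, maxit = maxit, hessian = hessian
      ))
    }
    V <- matrix(NA_real_, p + 1, p + 1)
    if (hessian) {
      H <- num_hessian(ztnb_score, opt$par, y = y, X = X, offset = offset)
      V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p + 1, p + 1))
    }
    beta <- opt$par[seq_len(p)]
    names(beta) <- colnames(X)
    vb <- V[seq_len(p), seq_len(p), drop = FALSE]
    dimnames(vb) <- list(colnames(X), colnames(X))
    out <- list(
      coefficients = beta, alpha = alpha_hat, theta = theta_hat,
      vcov = vb, vcov_full = V,
      loglik = -opt$value, loglik_init = ll0,
      converged = gn <= 1e-4, grad_norm = gn,
      family = "negbin", n = length(y)
    )
  } else {
    beta0 <- stats::coef(suppressWarnings(
      stats::glm.fit(X, y, offset = offset, family = stats::poisson())
    ))
    ll0 <- -ztpois_negll(beta0, y, X, offset)
    opt <- suppressWarnings(stats::optim(beta0, ztpois_negll, ztpois_score,
      y = y, X = X, offset = offset,
      method = "BFGS", control = list(maxit = maxit, reltol = 1e-14)
    ))
    gn <- sqrt(sum(ztpois_score(opt$par, y, X, offset)^2)) / length(y)
    if (gn > 1e-4) {
      stop(sprintf("truncated Poisson fit did not converge (score norm %.2e)", gn),
        call. = FALSE
      )
    }
    V <- matrix(NA_real_, p, p)
    if (hessian) {
      H <- num_hessian(ztpois_score, opt$par, y = y, X = X, offset = offset)
      V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
    }
    beta <- opt$par
    names(beta) <- colnames(X)
    dimnames(V) <- list(colnames(X), colnames(X))
    out <- list(
      coefficients = beta, alpha = 0, theta = Inf,
      vcov = V, vcov_full = V,
      loglik = -opt$value, loglik_init = ll0,
      converged = gn <= 1e-4, grad_norm = gn,
      family = "poisson", n = length(y)
    )
  }
  class(out) <- "truncated_glm"
  out
}

#' @export
print.truncated_glm <- function(x, ...) {
  cat(sprintf(
    "Zero-truncated %s regression (n = %d, logLik = %.2f, alpha = %.4g)\n",
    x$family, x$n, x$loglik, x$alpha
  ))
  print(round(x$coefficients, 4))
  invisible(x)
}
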