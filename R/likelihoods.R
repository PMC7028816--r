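#' Weakly informative prior set
#'
#' All three model families share the same weakly informative scheme:
#' `Normal(0, 2)` on slope coefficients, `Normal(0, 10)` on the intercept, and
#' a Half-Student-t(3, 0, scale) on the positive dispersion parameter -- scale
#' 25 for the beta precision and the NB2 dispersion, scale 2 for the residual
#' SD and the spline smoothness SD of the seasonal-trend model.
#'
#' @param slope_scale SD of the slope prior. Default 2.
#' @param intercept_scale SD of the intercept prior. Default 10.
#' @param dispersion_df Half-t degrees of freedom. Default 3.
#' @param dispersion_scale Half-t scale for the dispersion parameter.
#' @param spline_df,spline_scale Half-t prior on the spline smoothness SD
#'   (seasonal-trend family only).
#' @return A list of class `cf_prior_set`.
#' @export
prior_set <- function(slope_scale = 2, intercept_scale = 10,
                      dispersion_df = 3, dispersion_scale = 25,
                      spline_df = 3, spline_scale = 2) {
  stopifnot(slope_scale > 0, intercept_scale > 0, dispersion_df > 0,
            dispersion_scale > 0, spline_df > 0, spline_scale > 0)
  structure(list(slope_scale = slope_scale, intercept_scale = intercept_scale,
                 dispersion_df = dispersion_df,
                 dispersion_scale = dispersion_scale,
                 spline_df = spline_df, spline_scale = spline_scale),
            class = "cf_prior_set")
}

#' Counterfactual model specification
#'
#' Selects one of the three model families and bundles its priors and
#' design configuration:
#' \describe{
#'   \item{`beta`}{Beta regression with logit link on proportion outcomes,
#'     mean-precision parameterization; design from [build_search_design()]
#'     (reference main effects plus all pairwise interactions).}
#'   \item{`negbin`}{NB2 negative binomial GLM with log link on count
#'     outcomes; design from [build_import_design()] (main effects only),
#'     after [exclude_zero_dominated()].}
#'   \item{`seasonal_trend`}{Log-normal additive model for positive
#'     outcomes: month factor (January base) plus a penalized spline over
#'     standardized decimal time.}
#' }
#'
#' @param family `"beta"`, `"negbin"`, or `"seasonal_trend"`.
#' @param priors A [prior_set()]; defaults to the family's standard weakly
#'   informative set (Half-t scale 2 instead of 25 for `seasonal_trend`).
#' @param num_basis Spline basis dimension (seasonal-trend only). Default 10.
#' @param zero_threshold Zero-fraction above which a reference count series is
#'   dropped (negbin only). Default 0.5.
#' @param visits_unit Divisor applied to the outcome before logging in the
#'   seasonal-trend family, so coefficients sit on the prior scale. Default
#'   1e5 (the outcome is modelled per 100,000 visits).
#' @return An object of class `cf_model_spec`.
#' @export
model_spec <- function(family = c("beta", "negbin", "seasonal_trend"),
                       priors = NULL, num_basis = 10, zero_threshold = 0.5,
                       visits_unit = 1e5) {
  family <- match.arg(family)
  if (is.null(priors)) {
    priors <- if (family == "seasonal_trend") {
      prior_set(dispersion_scale = 2)
    } else {
      prior_set(dispersion_scale = 25)
    }
  }
  stopifnot(inherits(priors, "cf_prior_set"))
  structure(list(family = family, priors = priors, num_basis = num_basis,
                 zero_threshold = zero_threshold, visits_unit = visits_unit),
            class = "cf_model_spec")
}

#' @export
print.cf_model_spec <- function(x, ...) {
  cat("<cf_model_spec> family =", x$family, "\n")
  invisible(x)
}

spec_outcome_kind <- function(spec) {
  switch(spec$family, beta = "proportion", negbin = "count",
         seasonal_trend = "positive_real")
}

#' Parameter vector for a counterfactual model
#'
#' @param coefficients Named numeric vector, one entry per design column.
#' @param dispersion Positive scalar: beta precision, NB2 dispersion, or the
#'   residual SD of the seasonal-trend model.
#' @param spline_coeffs,spline_sd Spline coefficients and their SD
#'   (seasonal-trend only).
#' @return An object of class `cf_params`.
#' @export
param_vector <- function(coefficients, dispersion, spline_coeffs = NULL,
                         spline_sd = NULL) {
  stopifnot(is.numeric(coefficients), length(dispersion) == 1)
  structure(list(coefficients = coefficients, dispersion = dispersion,
                 spline_coeffs = spline_coeffs, spline_sd = spline_sd),
            class = "cf_params")
}

#' Convert mean-precision to shape parameters of the beta distribution
#'
#' The regression parameterization `Beta(mu, phi)` maps to the usual shapes
#' via `p = mu * phi` and `q = (1 - mu) * phi`, so `mu = p / (p + q)` is the
#' mean and `phi = p + q` the precision.
#'
#' @param mu Mean in (0, 1).
#' @param phi Precision, positive.
#' @return A list with shape components `p` and `q`.
#' @examples
#' beta_shapes_from_mean_precision(0.5, 4)
#' @export
beta_shapes_from_mean_precision <- function(mu, phi) {
  if (any(mu <= 0) || any(mu >= 1)) abort("mu must be strictly inside (0, 1)")
  if (any(phi <= 0)) abort("phi must be positive")
  list(p = mu * phi, q = (1 - mu) * phi)
}

#' Beta regression log-likelihood (mean-precision form)
#'
#' @param y Observations strictly inside (0, 1); boundary values must first
#'   go through [substitute_unit_boundary()].
#' @param mu Means in (0, 1), same length as `y` (or scalar).
#' @param phi Precision, positive scalar.
#' @return The summed log density.
#' @export
beta_loglik <- function(y, mu, phi) {
  if (any(y <= 0) || any(y >= 1)) {
    abort(paste("y must be strictly inside (0, 1);",
                "apply substitute_unit_boundary() first"))
  }
  sh <- beta_shapes_from_mean_precision(mu, phi)
  sum(dbeta(y, sh$p, sh$q, log = TRUE))
}

#' NB2 negative binomial log-likelihood
#'
#' The NB2 parameterization has mean `mu` and variance `mu + mu^2 / phi`;
#' smaller `phi` means more overdispersion, and as `phi` grows the
#' distribution approaches Poisson(`mu`).
#'
#' @param y Non-negative integer counts.
#' @param mu Positive means, same length as `y` (or scalar).
#' @param phi Dispersion, positive scalar.
#' @return The summed log probability mass.
#' @export
negbin_loglik <- function(y, mu, phi) {
  if (any(y < 0) || any(y != round(y))) {
    abort("y must be non-negative integers")
  }
  stopifnot(all(mu > 0), phi > 0)
  sum(dnbinom(y, size = phi, mu = mu, log = TRUE))
}

#' Seasonal-trend (log-normal additive) log-likelihood
#'
#' `log(y)` is Gaussian around a month effect (January base) plus a smooth
#' spline trend: `mu_i = M_i beta + s(T_i)`.
#'
#' @param y Positive outcomes (already divided by the unit, e.g. 1e5 visits).
#' @param month_index Integers 1-12, same length as `y`.
#' @param t_std Standardized decimal times (unused directly; the basis matrix
#'   already encodes them -- kept for interface clarity).
#' @param params A [param_vector()] with 12 coefficients (intercept + 11
#'   months), `spline_coeffs`, and `dispersion` = residual SD.
#' @param basis Spline basis matrix (rows match `y`).
#' @return The summed Gaussian log density of `log(y)`.
#' @export
seasonal_trend_loglik <- function(y, month_index, t_std, params, basis) {
  if (any(y <= 0)) abort("y must be positive")
  stopifnot(all(month_index %in% 1:12), length(month_index) == length(y))
  beta <- params$coefficients
  stopifnot(length(beta) == 12)
  M <- matrix(0, length(y), 12)
  M[, 1] <- 1
  for (j in 2:12) M[, j] <- as.numeric(month_index == j)
  eta <- drop(M %*% beta)
  if (!is.null(params$spline_coeffs)) {
    basis <- as.matrix(basis)
    stopifnot(nrow(basis) == length(y),
              ncol(basis) == length(params$spline_coeffs))
    eta <- eta + drop(basis %*% params$spline_coeffs)
  }
  sum(dnorm(log(y), eta, params$dispersion, log = TRUE))
}

#' Log prior density of a parameter vector
#'
#' Normal(0, `intercept_scale`) on the intercept, Normal(0, `slope_scale`) on
#' the remaining coefficients, Half-Student-t on the dispersion, and -- when
#' spline terms are present -- Normal(0, `spline_sd`) on each spline
#' coefficient with a Half-Student-t(`spline_df`, 0, `spline_scale`) on
#' `spline_sd` itself. Densities are on the natural scale (no change of
#' variables); a non-positive dispersion or spline SD yields `-Inf` rather
#' than an error.
#'
#' @param params A [param_vector()]; the first coefficient is the intercept.
#' @param priors A [prior_set()].
#' @return The log prior density (possibly `-Inf`).
#' @export
log_prior <- function(params, priors) {
  stopifnot(inherits(params, "cf_params"), inherits(priors, "cf_prior_set"))
  if (params$dispersion <= 0) return(-Inf)
  b <- params$coefficients
  lp <- dnorm(b[1], 0, priors$intercept_scale, log = TRUE)
  if (length(b) > 1) {
    lp <- lp + sum(dnorm(b[-1], 0, priors$slope_scale, log = TRUE))
  }
  lp <- lp + half_t_logpdf(params$dispersion, priors$dispersion_df,
                           priors$dispersion_scale)
  if (!is.null(params$spline_coeffs)) {
    if (is.null(params$spline_sd) || params$spline_sd <= 0) return(-Inf)
    lp <- lp + sum(dnorm(params$spline_coeffs, 0, params$spline_sd,
                         log = TRUE)) +
      half_t_logpdf(params$spline_sd, priors$spline_df, priors$spline_scale)
  }
  unname(lp)
}

# half-Student-t(df, 0, scale) density on x > 0 (doubled central t)
half_t_logpdf <- function(x, df, scale) {
  ifelse(x <= 0, -Inf, log(2) + dt(x / scale, df, log = TRUE) - log(scale))
}
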