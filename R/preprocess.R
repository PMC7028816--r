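#' Convert calendar dates to decimal years
#'
#' The decimal date of a day is `year + (day_of_year - 1) / days_in_year`,
#' with 366 days in leap years, so e.g. 2014-02-01 is 2014.085 (to three
#' decimals) and January 1st of any year is exactly the integer year.
#'
#' @param dates A `Date` vector (or ISO-8601 strings).
#' @return A numeric vector of decimal years, strictly monotone in the date.
#' @examples
#' to_decimal_date(as.Date("2014-02-01"))
#' @export
to_decimal_date <- function(dates) {
  if (is.character(dates)) {
    dates <- tryCatch(as.Date(dates), error = function(e) NA)
  }
  if (!inherits(dates, "Date") || anyNA(dates)) {
    abort("invalid calendar date input")
  }
  lt <- as.POSIXlt(dates)
  year <- lt$year + 1900L
  doy <- lt$yday  # 0-based day of year
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  year + doy / ifelse(leap, 366, 365)
}

#' Standardize dates for trend modelling
#'
#' Converts dates to decimal years, then centres on the mean and scales by
#' twice the standard deviation of the *fitting-period* decimal dates, so the
#' fitting-period values have mean 0 and sample SD 0.5 and regression
#' coefficients sit on a scale matched to weakly informative priors. The
#' centre and scale are frozen from `fit_dates`: post-intervention dates are
#' transformed with pre-intervention statistics so the counterfactual never
#' peeks at post data.
#'
#' @param dates Dates to transform.
#' @param fit_dates Dates defining the centre/scale (defaults to `dates`).
#' @return An object of class `cf_std_time` with fields `values`, `center`
#'   (decimal years) and `scale` (twice the sample SD, decimal years).
#' @export
standardize_time <- function(dates, fit_dates = dates) {
  dec_fit <- to_decimal_date(fit_dates)
  s <- sd(dec_fit)
  if (!is.finite(s) || s <= 0) {
    abort("fit_dates are constant; cannot standardize")
  }
  center <- mean(dec_fit)
  scale <- 2 * s
  structure(list(values = (to_decimal_date(dates) - center) / scale,
                 center = center, scale = scale),
            class = "cf_std_time")
}

#' Push unit-interval boundary values into the open interval
#'
#' The beta likelihood cannot accommodate exact 0s or 1s. The week at which a
#' relative search-frequency series attains its maximum of 1.0 is substituted
#' with `sub` (0.99 by default); exact zeros are substituted with `eps`
#' (0.005 by default) and a warning is emitted, since a zero would equally
#' break the likelihood. All interior values pass through unchanged, and the
#' transform is idempotent.
#'
#' @param series Numeric vector with values in `[0, 1]`.
#' @param sub Replacement for exact 1s. Default 0.99.
#' @param eps Replacement for exact 0s. Default 0.005.
#' @return The series with boundary values substituted, strictly in (0, 1).
#' @examples
#' substitute_unit_boundary(c(0.2, 1.0, 0.7))
#' @export
substitute_unit_boundary <- function(series, sub = 0.99, eps = 0.005) {
  if (any(series < 0) || any(series > 1)) {
    abort("series has values outside [0, 1]")
  }
  stopifnot(sub > 0, sub < 1, eps > 0, eps < 1)
  ones <- series == 1
  zeros <- series == 0
  if (any(zeros)) {
    warn(paste0("substituting ", eps, " for ", sum(zeros),
                " exact zero(s); the beta likelihood excludes 0"))
  }
  series[ones] <- sub
  series[zeros] <- eps
  series
}

#' Rescale a search-interest series to the unit interval
#'
#' Search-trend services deliver relative frequencies either on a 0-100 index
#' or already normalized to `[0, 1]`. Series with a maximum above 1 (and at or
#' below 100) are divided by 100; unit-scale series pass through unchanged.
#'
#' @param series Non-negative numeric vector.
#' @return The series on the `[0, 1]` scale.
#' @export
rescale_relative <- function(series) {
  if (any(series < 0)) abort("series has negative values")
  m <- max(series)
  if (m == 0) abort("all-zero series cannot be rescaled")
  if (m > 100) abort("series exceeds the 0-100 search-index scale")
  if (m > 1) series / 100 else series
}
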