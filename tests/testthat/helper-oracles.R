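# Independent oracles used by the sampler and impact tests. These never call
# the package's own likelihood/gradient path: densities come straight from
# stats::dbeta / stats::dnbinom / stats::dnorm.

half_t_ld <- function(x, df, scale) {
  log(2) + stats::dt(x / scale, df, log = TRUE) - log(scale)
}

# 2-D grid quadrature over (intercept, log dispersion) for an intercept-only
# model. log_post(b0, lphi) must be vectorized in its first argument.
quadrature_2d <- function(log_post, b0_range, lphi_range, n_grid = 241) {
  b0 <- seq(b0_range[1], b0_range[2], length.out = n_grid)
  lphi <- seq(lphi_range[1], lphi_range[2], length.out = n_grid)
  lp <- outer(b0, lphi, Vectorize(function(a, b) log_post(a, b)))
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  mb <- sum(w * b0)
  ml <- sum(t(w) * lphi)
  list(
    mean_b0 = mb,
    sd_b0 = sqrt(sum(w * (b0 - mb)^2)),
    mean_lphi = ml,
    sd_lphi = sqrt(sum(t(w) * (lphi - ml)^2))
  )
}

beta_intercept_logpost <- function(y) {
  function(b0, lphi) {
    mu <- stats::plogis(b0)
    phi <- exp(lphi)
    sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)) +
      stats::dnorm(b0, 0, 10, log = TRUE) + half_t_ld(phi, 3, 25) + lphi
  }
}

negbin_intercept_logpost <- function(y) {
  function(b0, lphi) {
    phi <- exp(lphi)
    sum(stats::dnbinom(y, size = phi, mu = exp(b0), log = TRUE)) +
      stats::dnorm(b0, 0, 10, log = TRUE) + half_t_ld(phi, 3, 25) + lphi
  }
}

# intercept-only design with n rows
intercept_design <- function(n) {
  cfimpact:::new_design(matrix(1, n, 1, dimnames = list(NULL, "intercept")),
                        includes_intercept = TRUE)
}

# a tiny deterministic proportion panel for interface tests
toy_panel <- function(n = 12, k = 2, seed = 42) {
  set.seed(seed)
  df <- tibble::tibble(
    date = seq(as.Date("2016-01-03"), by = "7 days", length.out = n)
  )
  df$focal <- stats::plogis(stats::rnorm(n, -1, 0.5))
  for (j in seq_len(k)) {
    df[[paste0("ref", j)]] <- stats::plogis(stats::rnorm(n, 0, 1))
  }
  panel(df, frequency = "weekly", outcome_kind = "proportion")
}
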