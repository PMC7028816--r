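test_that("mean-precision conversion matches its algebraic definition", {
  expect_equal(beta_shapes_from_mean_precision(0.5, 4), list(p = 2, q = 2))
  expect_equal(beta_shapes_from_mean_precision(0.25, 8), list(p = 2, q = 6))
  # round-trip (p, q) -> (mu, phi) -> (p, q)
  for (pq in list(c(2, 3), c(0.4, 9), c(7, 7))) {
    mu <- pq[1] / sum(pq); phi <- sum(pq)
    sh <- beta_shapes_from_mean_precision(mu, phi)
    expect_equal(c(sh$p, sh$q), pq)
  }
  expect_error(beta_shapes_from_mean_precision(1, 2), "inside")
  expect_error(beta_shapes_from_mean_precision(0.5, 0), "positive")
})

test_that("beta log-likelihood matches closed forms", {
  # mu = 0.5, phi = 2 is the uniform density: log-likelihood 0 everywhere
  for (y in c(0.5, 0.3, 0.911)) {
    expect_equal(beta_loglik(y, 0.5, 2), 0)
  }
  # Beta(3, 3) at 0.5 has density 1.875
  expect_equal(beta_loglik(0.5, 0.5, 6), log(1.875))
  expect_error(beta_loglik(c(0.2, 1), 0.5, 2), "substitute_unit_boundary")
  # invariant to joint row permutation
  set.seed(9)
  y <- runif(20, 0.05, 0.95); mu <- runif(20, 0.2, 0.8)
  perm <- sample(20)
  expect_equal(beta_loglik(y, mu, 7), beta_loglik(y[perm], mu[perm], 7))
})

test_that("NB2 log-likelihood matches its pmf and the Poisson limit", {
  # pmf at zero is (phi/(phi+mu))^phi
  expect_equal(negbin_loglik(0, 1, 1), log(0.5))
  expect_equal(negbin_loglik(3, 3, 1e6), dpois(3, 3, log = TRUE),
               tolerance = 1e-4)
  expect_error(negbin_loglik(2.5, 3, 1), "integers")
  expect_error(negbin_loglik(-1, 3, 1), "integers")
  set.seed(10)
  y <- rpois(15, 5); mu <- runif(15, 2, 9)
  perm <- sample(15)
  expect_equal(negbin_loglik(y, mu, 4), negbin_loglik(y[perm], mu[perm], 4))
})

test_that("NB2 and mean-precision beta draws match their moment formulas", {
  set.seed(11)
  n <- 1e5
  y <- rnbinom(n, size = 5, mu = 10)
  expect_equal(mean(y), 10, tolerance = 0.02)
  v_expect <- 10 + 100 / 5
  mc_se <- sd((y - mean(y))^2) / sqrt(n)
  expect_lt(abs(var(y) - v_expect), 3 * mc_se)

  sh <- beta_shapes_from_mean_precision(0.3, 12)
  b <- rbeta(n, sh$p, sh$q)
  expect_equal(mean(b), 0.3, tolerance = 0.005)
  expect_equal(var(b), 0.3 * 0.7 / (1 + 12), tolerance = 0.02)
})

test_that("seasonal-trend log-likelihood matches hand-computed Gaussians", {
  # zero residuals: all-January, intercept c, y = exp(c)
  n <- 9; cc <- 1.7
  par0 <- param_vector(c(cc, rep(0, 11)), dispersion = 1)
  ll <- seasonal_trend_loglik(rep(exp(cc), n), rep(1L, n), rep(0, n), par0,
                              basis = matrix(0, n, 0))
  expect_equal(ll, n * log(1 / sqrt(2 * pi)))

  # shift equivariance: intercept + a, log(y) + a
  set.seed(12)
  y <- exp(rnorm(6, 2, 0.3))
  m <- c(1L, 2L, 5L, 12L, 1L, 7L)
  pars <- param_vector(c(2, rnorm(11, 0, 0.2)), dispersion = 0.4)
  base <- seasonal_trend_loglik(y, m, rep(0, 6), pars, matrix(0, 6, 0))
  pars_shift <- pars
  pars_shift$coefficients[1] <- pars$coefficients[1] + 0.9
  expect_equal(seasonal_trend_loglik(y * exp(0.9), m, rep(0, 6), pars_shift,
                                     matrix(0, 6, 0)), base)

  # n = 3 case against a directly computed Gaussian log-density sum
  y3 <- c(3.2, 4.1, 2.7); m3 <- c(1L, 2L, 1L)
  beta <- c(1.1, 0.3, rep(0, 10)); sig <- 0.5
  eta <- c(1.1, 1.4, 1.1)
  manual <- sum(-0.5 * log(2 * pi * sig^2) - (log(y3) - eta)^2 / (2 * sig^2))
  p3 <- param_vector(beta, dispersion = sig)
  expect_equal(seasonal_trend_loglik(y3, m3, rep(0, 3), p3, matrix(0, 3, 0)),
               manual)

  # spline contribution enters through the basis
  Z <- matrix(c(1, -1, 0.5), 3, 1)
  p3s <- param_vector(beta, dispersion = sig, spline_coeffs = 0.2,
                      spline_sd = 1)
  manual_s <- sum(-0.5 * log(2 * pi * sig^2) -
                  (log(y3) - (eta + 0.2 * Z[, 1]))^2 / (2 * sig^2))
  expect_equal(seasonal_trend_loglik(y3, m3, rep(0, 3), p3s, Z), manual_s)
  expect_error(seasonal_trend_loglik(c(-1, 2, 3), m3, rep(0, 3), p3,
                                     matrix(0, 3, 0)), "positive")
})

test_that("log prior matches independent density evaluation", {
  pr <- prior_set()
  pars <- param_vector(setNames(rep(0, 5), letters[1:5]), dispersion = 25)
  manual <- dnorm(0, 0, 10, log = TRUE) + 4 * dnorm(0, 0, 2, log = TRUE) +
    half_t_ld(25, 3, 25)
  expect_equal(log_prior(pars, pr), manual)

  # moving one slope from 0 to 2 costs exactly 2^2 / (2 * 2^2) = 0.5
  pars2 <- pars
  pars2$coefficients[2] <- 2
  expect_equal(log_prior(pars, pr) - log_prior(pars2, pr), 0.5)

  # boundary dispersion signals -Inf rather than an error
  pars3 <- pars; pars3$dispersion <- 0
  expect_identical(log_prior(pars3, pr), -Inf)

  # spline block: iid normals given spline_sd plus its half-t
  pars4 <- param_vector(rep(0, 3), dispersion = 1,
                        spline_coeffs = c(0.5, -0.5), spline_sd = 0.8)
  manual4 <- dnorm(0, 0, 10, log = TRUE) + 2 * dnorm(0, 0, 2, log = TRUE) +
    half_t_ld(1, 3, 25) + sum(dnorm(c(0.5, -0.5), 0, 0.8, log = TRUE)) +
    half_t_ld(0.8, 3, 2)
  expect_equal(log_prior(pars4, prior_set()), manual4)
})

test_that("compiled log posterior agrees with the R likelihood + prior", {
  # the sampler's C++ target drops parameter-free constants, so compare
  # differences between parameter points, which must match exactly
  set.seed(13)

  # beta family
  p <- toy_panel(n = 20, k = 2)
  des <- build_search_design(p)
  y <- cfimpact:::panel_focal(p)
  spec <- model_spec("beta")
  data <- cfimpact:::sampler_data(spec, des, y)
  prior <- cfimpact:::sampler_prior_list(spec)
  r_lp <- function(th) {
    np <- ncol(des$matrix)
    stopifnot(length(th) == np + 1)
    beta_loglik(y, plogis(drop(des$matrix %*% th[1:np])), exp(th[np + 1])) +
      log_prior(param_vector(th[1:np], exp(th[np + 1])), spec$priors) +
      th[np + 1]  # log-scale Jacobian
  }
  t1 <- c(rnorm(4, 0, 0.3), log(12)); t2 <- c(rnorm(4, 0, 0.3), log(40))
  expect_equal(
    cfimpact:::cf_log_posterior("beta", data, prior, t1) -
      cfimpact:::cf_log_posterior("beta", data, prior, t2),
    r_lp(t1) - r_lp(t2), tolerance = 1e-8)

  # negbin family
  yc <- rpois(15, 50)
  desc <- intercept_design(15)
  specn <- model_spec("negbin")
  datan <- list(X = desc$matrix, y = yc, includes_intercept = TRUE)
  r_lpn <- function(th) {
    negbin_loglik(yc, exp(th[1] * desc$matrix[, 1]), exp(th[2])) +
      log_prior(param_vector(th[1], exp(th[2])), specn$priors) + th[2]
  }
  t1 <- c(3.5, log(3)); t2 <- c(4.1, log(20))
  expect_equal(
    cfimpact:::cf_log_posterior("negbin", datan, prior, t1) -
      cfimpact:::cf_log_posterior("negbin", datan, prior, t2),
    r_lpn(t1) - r_lpn(t2), tolerance = 1e-8)

  # seasonal family
  dates <- seq(as.Date("2010-01-01"), by = "1 month", length.out = 50)
  std <- standardize_time(dates)
  dess <- build_seasonal_design(dates, std)
  yv <- exp(rnorm(50, 2, 0.2))
  specs <- model_spec("seasonal_trend")
  datas <- cfimpact:::sampler_data(specs, dess, yv)
  priors <- cfimpact:::sampler_prior_list(specs)
  r_lps <- function(th) {
    q <- 10
    pv <- param_vector(th[1:12], dispersion = exp(th[24]),
                       spline_coeffs = th[13:22], spline_sd = exp(th[23]))
    seasonal_trend_loglik(yv, as.POSIXlt(dates)$mon + 1L, std$values, pv,
                          dess$spline$Z) +
      log_prior(pv, specs$priors) + th[23] + th[24]
  }
  t1 <- c(rnorm(12, 0, 0.3), rnorm(10, 0, 0.1), log(0.5), log(0.3))
  t2 <- c(rnorm(12, 0, 0.3), rnorm(10, 0, 0.1), log(1.2), log(0.1))
  expect_equal(
    cfimpact:::cf_log_posterior("seasonal_trend", datas, priors, t1) -
      cfimpact:::cf_log_posterior("seasonal_trend", datas, priors, t2),
    r_lps(t1) - r_lps(t2), tolerance = 1e-8)

  # gradients match numerical differentiation of the compiled target
  th0 <- c(rnorm(4, 0, 0.2), log(15))
  g <- cfimpact:::cf_log_posterior_grad("beta", data, prior, th0)
  num <- vapply(seq_along(th0), function(j) {
    h <- 1e-6
    tp <- th0; tp[j] <- tp[j] + h
    tm <- th0; tm[j] <- tm[j] - h
    (cfimpact:::cf_log_posterior("beta", data, prior, tp) -
       cfimpact:::cf_log_posterior("beta", data, prior, tm)) / (2 * h)
  }, numeric(1))
  expect_equal(g, num, tolerance = 1e-4)
})
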