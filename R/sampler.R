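#' Sampler configuration
#'
#' Defaults follow the study design: 4 chains of 2000 iterations each with the
#' first half discarded as warm-up.
#'
#' @param chains Number of chains, at least 2. Default 4.
#' @param iterations Iterations per chain (even). Default 2000.
#' @param warmup_fraction Fraction discarded as warm-up, in (0, 1). Default 0.5.
#' @param seed Integer seed; all chain randomness derives from it.
#' @param max_treedepth NUTS doubling limit. Default 10.
#' @param target_accept Dual-averaging target acceptance. Default 0.8.
#' @return An object of class `cf_sampler_config`.
#' @export
sampler_config <- function(chains = 4, iterations = 2000,
                           warmup_fraction = 0.5, seed = 1,
                           max_treedepth = 10, target_accept = 0.8) {
  stopifnot(chains >= 2, iterations %% 2 == 0,
            warmup_fraction > 0, warmup_fraction < 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup_fraction = warmup_fraction,
                 seed = as.integer(seed),
                 max_treedepth = as.integer(max_treedepth),
                 target_accept = target_accept),
            class = "cf_sampler_config")
}

# deterministic sub-seeds so each pipeline stage has its own stream
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + salt * 7919) %% (2^31 - 2)) + 1L
}

sampler_data <- function(spec, design, y) {
  if (spec$family == "seasonal_trend") {
    list(Xf = design$matrix, Z = design$spline$Z,
         logy = log(y), includes_intercept = design$includes_intercept)
  } else {
    list(X = design$matrix, y = as.numeric(y),
         includes_intercept = design$includes_intercept)
  }
}

sampler_param_names <- function(spec, design) {
  if (spec$family == "seasonal_trend") {
    c(design$names, colnames(design$spline$Z), "spline_sd", "sigma")
  } else {
    c(design$names, "phi")
  }
}

# indices of parameters sampled on the log scale
positive_params <- function(spec, d) {
  if (spec$family == "seasonal_trend") c(d - 1L, d) else d
}

sampler_prior_list <- function(spec) {
  pr <- spec$priors
  list(intercept_scale = pr$intercept_scale, slope_scale = pr$slope_scale,
       dispersion_df = pr$dispersion_df,
       dispersion_scale = pr$dispersion_scale,
       spline_df = pr$spline_df, spline_scale = pr$spline_scale)
}

#' Sample from the posterior of a counterfactual model
#'
#' Runs the package's No-U-Turn sampler over the unnormalized log posterior
#' (log-likelihood plus log prior) of the given model family. Positive
#' parameters (precision/dispersion, residual SD, spline SD) are sampled on
#' the log scale with the Jacobian correction and returned on the natural
#' scale. With `y` of length zero the likelihood vanishes and the draws come
#' from the prior alone.
#'
#' Chains are initialized at dispersed points: coefficients drawn from
#' Normal(0, 0.1) scaled down by the magnitude of the corresponding predictor
#' column (raw count predictors would otherwise overflow the linear
#' predictor), and dispersions at the prior median, jittered per chain.
#'
#' @param spec A [model_spec()].
#' @param design A design-matrix object built from the pre-intervention panel.
#' @param y Outcome series (pre-intervention; already on the model scale for
#'   the seasonal-trend family).
#' @param config A [sampler_config()].
#' @return An object of class `cf_posterior` with the draws array
#'   `[iteration, chain, parameter]`.
#' @export
sample_posterior <- function(spec, design, y, config = sampler_config()) {
  stopifnot(inherits(spec, "cf_model_spec"), inherits(design, "cf_design"),
            inherits(config, "cf_sampler_config"))
  n <- nrow(design$matrix)
  if (length(y) != n) abort("design rows and outcome length differ")
  if (spec$family == "beta" && n > 0 && (any(y <= 0) || any(y >= 1))) {
    abort("beta outcomes must lie strictly inside (0, 1)")
  }
  data <- sampler_data(spec, design, y)
  prior <- sampler_prior_list(spec)
  pnames <- sampler_param_names(spec, design)
  d <- length(pnames)
  pos <- positive_params(spec, d)
  n_coef <- d - length(pos)

  # scale-aware initialization and mass-matrix preconditioning
  col_scale <- rep(1, n_coef)
  if (spec$family != "seasonal_trend" && n > 0) {
    col_scale <- pmax(1, apply(abs(design$matrix), 2, max))
  } else if (spec$family == "seasonal_trend" && n > 0) {
    col_scale <- pmax(1, c(apply(abs(design$matrix), 2, max),
                           apply(abs(design$spline$Z), 2, max)))
  }
  disp_median <- spec$priors$dispersion_scale * qt(0.75, spec$priors$dispersion_df)
  spl_median <- spec$priors$spline_scale * qt(0.75, spec$priors$spline_df)
  inv_mass0 <- c((1 / col_scale)^2, rep(1, length(pos)))

  warmup <- as.integer(round(config$iterations * config$warmup_fraction))
  n_keep <- config$iterations - warmup
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$chains)

  draws <- array(NA_real_, c(n_keep, config$chains, d),
                 dimnames = list(NULL, NULL, pnames))
  lp <- matrix(NA_real_, n_keep, config$chains)
  n_divergent <- integer(config$chains)

  for (ch in seq_len(config$chains)) {
    set.seed(chain_seeds[ch])
    init <- NULL
    for (try in seq_len(100)) {
      cand <- c(rnorm(n_coef, 0, 0.1) / col_scale,
                log(c(disp_median, spl_median)[seq_along(pos)]) +
                  rnorm(length(pos), 0, 0.2))
      if (spec$family == "seasonal_trend") {
        # theta order: coefficients, spline coeffs, log tau, log sigma
        cand[(d - 1):d] <- log(c(spl_median, disp_median)) +
          rnorm(2, 0, 0.2)
      }
      if (is.finite(cf_log_posterior(spec$family, data, prior, cand))) {
        init <- cand
        break
      }
    }
    if (is.null(init)) {
      abort("non-finite log posterior at initialization after 100 retries")
    }
    res <- nuts_run(spec$family, data, prior, init, inv_mass0,
                    config$iterations, warmup, config$max_treedepth,
                    config$target_accept)
    m <- res$draws
    m[, pos] <- exp(m[, pos, drop = FALSE])
    draws[, ch, ] <- m
    lp[, ch] <- res$lp
    n_divergent[ch] <- res$n_divergent
  }
  structure(list(draws = draws, parameter_names = pnames, config = config,
                 family = spec$family, spec = spec,
                 design_names = design$names,
                 lp = lp, n_divergent = n_divergent),
            class = "cf_posterior")
}

#' @export
print.cf_posterior <- function(x, ...) {
  dm <- dim(x$draws)
  cat("<cf_posterior> family =", x$family, ":", dm[2], "chains x", dm[1],
      "kept draws,", dm[3], "parameters\n")
  invisible(x)
}

# flattened draws: (chains * iterations) x parameters
posterior_matrix <- function(samples) {
  dm <- dim(samples$draws)
  out <- matrix(aperm(samples$draws, c(1, 2, 3)), dm[1] * dm[2], dm[3])
  colnames(out) <- samples$parameter_names
  out
}

#' @rdname sample_posterior
#' @param x A `cf_posterior` object.
#' @param ... Unused.
#' @export
tidy.cf_posterior <- function(x, ...) {
  m <- posterior_matrix(x)
  conv <- check_convergence(x)
  tibble::tibble(
    term = colnames(m),
    estimate = apply(m, 2, median),
    std.error = apply(m, 2, sd),
    conf.low = apply(m, 2, quantile, 0.05),
    conf.high = apply(m, 2, quantile, 0.95),
    rhat = conv$diagnostics$rhat,
    n_eff = conv$diagnostics$n_eff
  )
}

#' Export posterior draws to CSV
#'
#' One row per retained draw with `chain` and `iteration` columns followed by
#' one column per parameter.
#'
#' @param samples A `cf_posterior`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(samples, path) {
  dm <- dim(samples$draws)
  long <- do.call(rbind, lapply(seq_len(dm[2]), function(ch) {
    cbind(chain = ch, iteration = seq_len(dm[1]), samples$draws[, ch, ])
  }))
  readr::write_csv(tibble::as_tibble(as.data.frame(long)), path)
  invisible(path)
}

#' Split-chain potential scale reduction factor
#'
#' Each chain is halved and the classic between/within variance ratio is
#' computed over the split halves, a strengthening of the classic diagnostic
#' that also detects within-chain drift. Values near 1 indicate convergence;
#' the gate used downstream is 1.05.
#'
#' @param draws A matrix of draws, iterations x chains (at least 2 chains of
#'   at least 4 draws), or a numeric vector list convertible to one.
#' @return The split-chain R-hat (possibly `Inf` when all chains are
#'   degenerate).
#' @export
compute_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (ncol(draws) < 2 || n < 4) abort("need >= 2 chains of >= 4 draws")
  half <- floor(n / 2)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split)
  nn <- nrow(split)
  W <- mean(apply(split, 2, var))
  B <- nn * var(colMeans(split))
  if (!is.finite(W) || W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Effective sample size
#'
#' Autocorrelation-based effective sample size combined across chains, using
#' the split-chain variance estimate and Geyer's initial monotone positive
#' pair truncation of the autocorrelation sum.
#'
#' @inheritParams compute_rhat
#' @return The effective sample size (0 for constant draws).
#' @export
compute_n_eff <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  m <- ncol(draws)
  if (m < 2 || n < 4) abort("need >= 2 chains of >= 4 draws")
  ch_var <- apply(draws, 2, var)
  W <- mean(ch_var)
  B <- n * var(colMeans(draws))
  var_plus <- (n - 1) / n * W + B / n
  if (!is.finite(var_plus) || var_plus == 0) return(0)
  # per-chain autocovariances
  acov <- vapply(seq_len(m), function(j) {
    a <- acf(draws[, j], lag.max = n - 1, type = "covariance",
             plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  }, numeric(n))
  rho <- 1 - (W - rowMeans(acov[-1, , drop = FALSE])) / var_plus
  # Geyer initial positive sequence over lag pairs
  max_pairs <- floor((length(rho) - 1) / 2)
  tau <- 1
  prev <- Inf
  t <- 1
  P0 <- 1 + rho[1]
  P0 <- min(P0, prev)
  tau <- -1 + 2 * P0
  prev <- P0
  k <- 1
  while (2 * k + 1 <= length(rho)) {
    P <- rho[2 * k] + rho[2 * k + 1]
    if (!is.finite(P) || P <= 0) break
    P <- min(P, prev)  # enforce monotone decrease
    tau <- tau + 2 * P
    prev <- P
    k <- k + 1
  }
  max(m * n / tau, 0)
}

#' Convergence report for posterior samples
#'
#' Per-parameter split-chain R-hat and effective sample size with the study's
#' gate: all R-hat below 1.05 and all n_eff above 100. Downstream impact
#' evaluation refuses fits that fail the gate unless forced.
#'
#' @param samples A `cf_posterior`.
#' @param rhat_max,n_eff_min Gate thresholds. Defaults 1.05 and 100.
#' @return An object of class `cf_convergence` with a `diagnostics` tibble
#'   and a `passed` flag.
#' @export
check_convergence <- function(samples, rhat_max = 1.05, n_eff_min = 100) {
  stopifnot(inherits(samples, "cf_posterior"))
  d <- dim(samples$draws)[3]
  rhat <- numeric(d)
  neff <- numeric(d)
  for (j in seq_len(d)) {
    dm <- samples$draws[, , j, drop = TRUE]
    rhat[j] <- compute_rhat(dm)
    neff[j] <- compute_n_eff(dm)
  }
  diagnostics <- tibble::tibble(parameter = samples$parameter_names,
                                rhat = rhat, n_eff = neff)
  structure(list(diagnostics = diagnostics,
                 passed = all(rhat < rhat_max) && all(neff > n_eff_min),
                 rhat_max = rhat_max, n_eff_min = n_eff_min,
                 n_divergent = sum(samples$n_divergent)),
            class = "cf_convergence")
}

#' @export
print.cf_convergence <- function(x, ...) {
  cat("<cf_convergence>", if (x$passed) "PASSED" else "FAILED",
      sprintf("(max rhat %.3f, min n_eff %.0f, %d divergent)\n",
              max(x$diagnostics$rhat), min(x$diagnostics$n_eff),
              x$n_divergent))
  invisible(x)
}

worst_parameters <- function(conv, k = 3) {
  d <- conv$diagnostics
  d <- d[order(-d$rhat, d$n_eff), ]
  paste0(utils::head(d$parameter, k), " (rhat=",
         sprintf("%.3f", utils::head(d$rhat, k)), ", n_eff=",
         sprintf("%.0f", utils::head(d$n_eff, k)), ")", collapse = "; ")
}
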