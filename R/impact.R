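#' Posterior predictive forecast over a design
#'
#' For every retained posterior draw the linear predictor is pushed through
#' the family's inverse link and one outcome is simulated from the observation
#' distribution: `Beta(mu*phi, (1-mu)*phi)` for proportions, NB2 for counts,
#' and `exp(Normal(mu, sigma)) * visits_unit` for the seasonal-trend family.
#' The result combines parameter and observation noise -- the full predictive
#' band, not just the fitted mean.
#'
#' @param samples A `cf_posterior` from [sample_posterior()].
#' @param spec The [model_spec()] used for the fit.
#' @param post_design Design built over the forecast rows with pre-period
#'   standardization constants (column set must match the fit design).
#' @param times Dates of the forecast rows.
#' @param rng_seed Integer seed for the observation noise.
#' @return An object of class `cf_predictive`: `times` plus a draws matrix
#'   (posterior draw x time point) on the observation scale.
#' @export
posterior_predict <- function(samples, spec, post_design, times = NULL,
                              rng_seed = 1) {
  stopifnot(inherits(samples, "cf_posterior"), inherits(post_design, "cf_design"))
  if (!identical(post_design$names, samples$design_names)) {
    abort("post_design columns do not match the fitted design")
  }
  m <- posterior_matrix(samples)
  X <- post_design$matrix
  nt <- nrow(X)
  if (is.null(times)) times <- seq_len(nt)
  p <- ncol(X)
  set.seed(rng_seed)
  B <- m[, seq_len(p), drop = FALSE]
  eta <- B %*% t(X)  # draws x time
  nd <- nrow(m)
  draws <- switch(
    samples$family,
    beta = {
      phi <- m[, "phi"]
      mu <- plogis(eta)
      matrix(rbeta(length(mu), mu * phi, (1 - mu) * phi), nd, nt)
    },
    negbin = {
      phi <- m[, "phi"]
      mu <- exp(eta)
      matrix(rnbinom(length(mu), size = phi, mu = mu), nd, nt)
    },
    seasonal_trend = {
      q <- ncol(post_design$spline$Z)
      bs <- m[, p + seq_len(q), drop = FALSE]
      eta <- eta + bs %*% t(post_design$spline$Z)
      sigma <- m[, "sigma"]
      exp(eta + matrix(rnorm(length(eta)), nd, nt) * sigma) *
        spec$visits_unit
    },
    abort("unknown family")
  )
  structure(list(times = times, draws = draws, family = samples$family),
            class = "cf_predictive")
}

#' @export
print.cf_predictive <- function(x, ...) {
  cat("<cf_predictive>", nrow(x$draws), "draws x", ncol(x$draws),
      "time points (", x$family, ")\n")
  invisible(x)
}

#' Observed-to-expected effect ratio
#'
#' Divides the observed outcome by each posterior-predictive draw and reports
#' the median and equal-tailed 50% and 90% credible intervals of the ratio.
#' Values above 1 mean the observation was higher than the counterfactual
#' expectation. Predictive draws equal to zero (possible for counts) are
#' excluded from the ratio distribution; their number is reported.
#'
#' @param observed Observed outcome at one time point.
#' @param predictive_draws Posterior-predictive draws at that time point.
#' @return A one-row tibble: `ratio_median`, `ratio_lo50`, `ratio_hi50`,
#'   `ratio_lo90`, `ratio_hi90`, `n_zero_draws`.
#' @export
effect_ratio <- function(observed, predictive_draws) {
  zero <- predictive_draws == 0
  keep <- predictive_draws[!zero]
  if (length(keep) == 0) {
    abort("all predictive draws are zero; the effect ratio is undefined")
  }
  r <- observed / keep
  q <- quantile(r, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE, type = 7)
  tibble::tibble(ratio_median = q[3], ratio_lo50 = q[2], ratio_hi50 = q[4],
                 ratio_lo90 = q[1], ratio_hi90 = q[5],
                 n_zero_draws = sum(zero))
}

#' Exceedance probability
#'
#' Posterior-predictive probability that the observation is higher than
#' expected: the fraction of predictive draws strictly below the observed
#' value plus half the fraction exactly equal (mid-probability rule, relevant
#' for discrete counts).
#'
#' @inheritParams effect_ratio
#' @return A probability in `[0, 1]`.
#' @export
exceedance_probability <- function(observed, predictive_draws) {
  mean(predictive_draws < observed) + 0.5 * mean(predictive_draws == observed)
}

summarize_impact <- function(times, observed, pred) {
  purrr::map_dfr(seq_along(times), function(i) {
    dr <- pred$draws[, i]
    dplyr::bind_cols(
      tibble::tibble(date = times[i], observed = observed[i],
                     expected_median = median(dr)),
      effect_ratio(observed[i], dr),
      tibble::tibble(p_exceed = exceedance_probability(observed[i], dr))
    )
  })
}

#' Counterfactual impact evaluation
#'
#' The end-to-end procedure: split the study at the intervention date,
#' preprocess the focal series for the family (unit-boundary substitution for
#' proportions, zero-dominated reference exclusion for counts, frozen
#' pre-period time standardization for the seasonal-trend model), fit the
#' counterfactual regression to pre-intervention data only, forecast the
#' post-intervention window from the posterior predictive distribution, and
#' summarise the per-period observed/expected ratio and exceedance
#' probability. Pre-period predictive bands are also computed for display.
#'
#' @param study An [intervention_study()].
#' @param spec A [model_spec()] matching the panel's outcome kind.
#' @param config A [sampler_config()].
#' @param force Evaluate even when the convergence gate fails. Default FALSE.
#' @return An object of class `cf_impact` with the per-period `summary`
#'   tibble, the `convergence` report, posterior `samples`, the post-period
#'   `predictive`, a pre-period predictive (`pre_predictive`), and processing
#'   `notes`.
#' @export
evaluate_impact <- function(study, spec, config = sampler_config(),
                            force = FALSE) {
  stopifnot(inherits(study, "cf_study"), inherits(spec, "cf_model_spec"))
  pan <- study$panel
  if (attr(pan, "outcome_kind") != spec_outcome_kind(spec)) {
    abort(paste0("family `", spec$family, "` expects outcome_kind `",
                 spec_outcome_kind(spec), "` but the panel is `",
                 attr(pan, "outcome_kind"), "`"))
  }
  notes <- character()
  focal_col <- attr(pan, "focal_col")
  if (spec$family == "beta") {
    foc <- rescale_relative(panel_focal(pan))
    n_bound <- sum(foc %in% c(0, 1))
    if (n_bound > 0) {
      notes <- c(notes, paste0("substituted ", n_bound,
                               " unit-boundary focal value(s)"))
    }
    pan <- panel_set(pan, focal_col,
                     withCallingHandlers(substitute_unit_boundary(foc),
                                         warning = function(w) invokeRestart("muffleWarning")))
  }
  if (spec$family == "negbin") {
    pan <- suppressMessages(exclude_zero_dominated(pan, spec$zero_threshold))
    if (length(attr(pan, "dropped_refs")) > 0) {
      notes <- c(notes, paste0("dropped zero-dominated reference(s): ",
                               paste(attr(pan, "dropped_refs"),
                                     collapse = ", ")))
    }
  }
  study2 <- intervention_study(pan, study$intervention_date)
  sp <- split_pre_post(study2)

  if (spec$family == "seasonal_trend") {
    std <- standardize_time(panel_dates(sp$pre))
    design_pre <- build_seasonal_design(panel_dates(sp$pre), std,
                                        num_basis = spec$num_basis)
    design_post <- build_seasonal_design(panel_dates(sp$post), std,
                                         basis = design_pre$spline$basis)
    y_pre <- panel_focal(sp$pre) / spec$visits_unit
  } else {
    builder <- if (spec$family == "beta") build_search_design else build_import_design
    design_pre <- builder(sp$pre)
    design_post <- builder(sp$post)
    y_pre <- panel_focal(sp$pre)
  }
  p_total <- design_ncol(design_pre)
  if (nrow(sp$pre) < 2 * p_total) {
    abort(paste0("pre-intervention period has ", nrow(sp$pre),
                 " observations but the design has ", p_total,
                 " columns; need at least ", 2 * p_total))
  }

  samples <- sample_posterior(spec, design_pre, y_pre, config)
  conv <- check_convergence(samples)
  if (!conv$passed && !force) {
    abort(paste0("convergence gate failed (rhat < ", conv$rhat_max,
                 ", n_eff > ", conv$n_eff_min, "); worst: ",
                 worst_parameters(conv),
                 ". Re-run with more iterations or force = TRUE."))
  }
  pred <- posterior_predict(samples, spec, design_post,
                            times = panel_dates(sp$post),
                            rng_seed = derive_seed(config$seed, 2))
  pre_pred <- posterior_predict(samples, spec, design_pre,
                                times = panel_dates(sp$pre),
                                rng_seed = derive_seed(config$seed, 3))
  observed_post <- panel_focal(sp$post)
  summary <- summarize_impact(panel_dates(sp$post), observed_post, pred)
  structure(list(summary = summary, convergence = conv, samples = samples,
                 predictive = pred, pre_predictive = pre_pred,
                 study = study2, spec = spec, notes = notes,
                 observed_pre = panel_focal(sp$pre)),
            class = "cf_impact")
}

#' @export
print.cf_impact <- function(x, ...) {
  cat("<cf_impact> family =", x$spec$family, "\n")
  print(x$convergence)
  print(x$summary, n = 5)
  invisible(x)
}

#' @rdname evaluate_impact
#' @param x A `cf_impact` object.
#' @param ... Unused.
#' @export
tidy.cf_impact <- function(x, ...) x$summary

#' @rdname evaluate_impact
#' @export
glance.cf_impact <- function(x, ...) {
  tibble::tibble(
    family = x$spec$family,
    n_pre = length(x$observed_pre),
    n_post = nrow(x$summary),
    converged = x$convergence$passed,
    max_rhat = max(x$convergence$diagnostics$rhat),
    min_n_eff = min(x$convergence$diagnostics$n_eff),
    p_exceed_first = x$summary$p_exceed[1],
    ratio_median_first = x$summary$ratio_median[1]
  )
}

#' Write an impact summary to CSV
#'
#' Columns: `date, observed, expected_median, ratio_median, ratio_lo50,
#' ratio_hi50, ratio_lo90, ratio_hi90, p_exceed`.
#'
#' @param impact A `cf_impact` (or its summary tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_impact <- function(impact, path) {
  s <- if (inherits(impact, "cf_impact")) impact$summary else impact
  cols <- c("date", "observed", "expected_median", "ratio_median",
            "ratio_lo50", "ratio_hi50", "ratio_lo90", "ratio_hi90",
            "p_exceed")
  readr::write_csv(s[, cols], path)
  invisible(path)
}
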