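test_that("effect ratio summarises observed / predictive draws", {
  r <- effect_ratio(2, c(1, 2, 4))
  expect_equal(r$ratio_median, 1)
  expect_equal(r$n_zero_draws, 0)

  # observed equal to every draw: all bands collapse at 1
  r1 <- effect_ratio(3.3, rep(3.3, 50))
  expect_true(all(unlist(r1[, 1:5]) == 1))

  # quantiles match an independent direct re-computation on the same draws
  set.seed(31)
  dr <- rnbinom(4000, size = 2, mu = 5)
  r2 <- effect_ratio(10, dr)
  direct <- quantile(10 / dr[dr > 0], c(0.05, 0.25, 0.5, 0.75, 0.95),
                     names = FALSE)
  expect_equal(unlist(r2[, c("ratio_lo90", "ratio_lo50", "ratio_median",
                             "ratio_hi50", "ratio_hi90")], use.names = FALSE),
               direct)
  expect_equal(r2$n_zero_draws, sum(dr == 0))
  expect_error(effect_ratio(1, c(0, 0)), "zero")

  # interval nesting invariant
  expect_lte(r2$ratio_lo90, r2$ratio_lo50)
  expect_lte(r2$ratio_lo50, r2$ratio_median)
  expect_lte(r2$ratio_median, r2$ratio_hi50)
  expect_lte(r2$ratio_hi50, r2$ratio_hi90)
})

test_that("exceedance probability uses the mid-probability tie rule", {
  expect_equal(exceedance_probability(9, c(1, 2, 3)), 1)
  expect_equal(exceedance_probability(2, c(2, 2, 4, 4)), 0.25)
  set.seed(32)
  dr <- rnorm(10001)
  expect_equal(exceedance_probability(median(dr), dr), 0.5, tolerance = 1e-3)
  # monotone non-decreasing in the observed value
  obs <- seq(-3, 3, length.out = 25)
  pe <- vapply(obs, exceedance_probability, numeric(1),
               predictive_draws = dr)
  expect_true(all(diff(pe) >= 0))
})

test_that("ratio and exceedance are invariant to a common positive rescaling", {
  set.seed(33)
  dr <- rlnorm(2000, 0, 0.4)
  obs <- 1.7
  for (c_scale in c(0.01, 3, 1e5)) {
    r0 <- effect_ratio(obs, dr)
    r1 <- effect_ratio(obs * c_scale, dr * c_scale)
    expect_equal(as.numeric(r1[, 1:5]), as.numeric(r0[, 1:5]))
    expect_equal(exceedance_probability(obs * c_scale, dr * c_scale),
                 exceedance_probability(obs, dr))
  }
})

test_that("posterior prediction respects the family's observation model", {
  # degenerate posterior: manufacture a point-mass cf_posterior
  point_post <- function(b, phi, names, family) {
    d <- length(b) + 1
    draws <- array(rep(c(b, phi), each = 2000), c(1000, 2, d),
                   dimnames = list(NULL, NULL, c(names, "phi")))
    structure(list(draws = draws, parameter_names = c(names, "phi"),
                   family = family, design_names = names,
                   n_divergent = 0L),
              class = "cf_posterior")
  }
  X <- cbind(intercept = rep(1, 3), x = c(-1, 0, 1))
  des <- cfimpact:::new_design(X, includes_intercept = TRUE)

  # beta with enormous precision concentrates at plogis(X beta)
  sp <- point_post(c(0.4, 0.8), 1e7, colnames(X), "beta")
  pred <- posterior_predict(sp, model_spec("beta"), des, rng_seed = 7)
  expect_equal(dim(pred$draws), c(2000, 3))
  expect_equal(colMeans(pred$draws), plogis(c(-0.4, 0.4, 1.2)),
               tolerance = 1e-3)
  expect_true(all(pred$draws > 0 & pred$draws < 1))

  # negbin: predictive mean matches exp(X beta) (law of total expectation)
  sn <- point_post(c(3, 0.5), 8, colnames(X), "negbin")
  predn <- posterior_predict(sn, model_spec("negbin"), des, rng_seed = 8)
  expect_true(all(predn$draws >= 0 & predn$draws == round(predn$draws)))
  mu <- exp(c(2.5, 3, 3.5))
  expect_equal(colMeans(predn$draws), mu, tolerance = 0.05)

  # seeded prediction is reproducible; different seed differs
  predn2 <- posterior_predict(sn, model_spec("negbin"), des, rng_seed = 8)
  expect_identical(predn$draws, predn2$draws)
  predn3 <- posterior_predict(sn, model_spec("negbin"), des, rng_seed = 9)
  expect_false(identical(predn$draws, predn3$draws))

  # mismatched design columns are rejected
  des_bad <- cfimpact:::new_design(
    cbind(intercept = rep(1, 3), z = 1:3), includes_intercept = TRUE)
  expect_error(posterior_predict(sn, model_spec("negbin"), des_bad),
               "match")
})

test_that("evaluate_impact rejects a family/outcome mismatch", {
  g <- generate_import_panel(scenario_config("imports", seed = 2))
  expect_error(evaluate_impact(g$study, model_spec("beta")), "outcome_kind")
})

test_that("evaluate_impact produces a coherent per-period summary", {
  g <- generate_import_panel(scenario_config("imports", seed = 5))
  res <- evaluate_impact(g$study, model_spec("negbin"),
                         sampler_config(iterations = 600, seed = 17))
  s <- res$summary
  expect_equal(nrow(s), 6)
  expect_true(all(s$p_exceed >= 0 & s$p_exceed <= 1))
  expect_true(all(s$ratio_lo90 <= s$ratio_lo50 &
                  s$ratio_lo50 <= s$ratio_median &
                  s$ratio_median <= s$ratio_hi50 &
                  s$ratio_hi50 <= s$ratio_hi90))
  expect_identical(s$date, split_pre_post(g$study)$post$date)
  expect_identical(tidy(res), s)
  g1 <- glance(res)
  expect_true(g1$converged)
  expect_equal(g1$n_post, 6)
  # CSV export honours the documented column order
  path <- withr::local_tempfile(fileext = ".csv")
  write_impact(res, path)
  expect_identical(
    names(readr::read_csv(path, show_col_types = FALSE)),
    c("date", "observed", "expected_median", "ratio_median", "ratio_lo50",
      "ratio_hi50", "ratio_lo90", "ratio_hi90", "p_exceed"))
  # plots build without error
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(res, type = "ratio"), "ggplot")
})

test_that("a short pre-period refuses to fit", {
  g <- generate_search_panel(scenario_config("search", seed = 6))
  pan <- g$study$panel
  st <- intervention_study(pan, pan$date[10])  # 9 pre rows, 8 design columns
  expect_error(evaluate_impact(st, model_spec("beta")), "at least")
})
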