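test_that("generators are pure functions of the configuration", {
  for (kind in c("search", "imports", "visits")) {
    cfg <- scenario_config(kind, seed = 14)
    g1 <- generate_scenario(cfg)
    g2 <- generate_scenario(cfg)
    expect_identical(g1$study$panel, g2$study$panel)
    expect_identical(g1$truth$coefficients, g2$truth$coefficients)
    g3 <- generate_scenario(scenario_config(kind, seed = 15))
    expect_false(identical(g1$study$panel, g3$study$panel))
    # every generated panel satisfies its own invariants (the constructor
    # revalidates)
    expect_s3_class(panel(tibble::as_tibble(as.data.frame(g1$study$panel)),
                          frequency = attr(g1$study$panel, "frequency"),
                          outcome_kind = attr(g1$study$panel, "outcome_kind")),
                    "cf_panel")
  }
})

test_that("search panels are unit-normalized proportions with known truth", {
  cfg <- scenario_config("search", seed = 16)
  g <- generate_search_panel(cfg)
  pan <- g$study$panel
  expect_equal(max(pan$focal), 1.0)
  expect_true(all(pan$focal >= 0 & pan$focal <= 1))
  expect_equal(nrow(pan), 120)
  expect_equal(length(attr(pan, "ref_cols")), 3)
  # truth covers every design column
  des <- build_search_design(pan)
  expect_identical(names(g$truth$coefficients), des$names)
  expect_equal(g$truth$effect_profile, rep(1, 10))

  # a null effect profile leaves the generated data identical to the null
  g_null <- generate_search_panel(scenario_config("search", seed = 16,
                                                  effect_profile = rep(1, 5)))
  expect_identical(g_null$study$panel, pan)

  # an injected effect changes only the post period (pre-normalization the
  # pre period is untouched; compare pre-period ranks which survive scaling)
  g_eff <- generate_search_panel(scenario_config("search", seed = 16,
                                                 effect_profile = transient_effect(2.1, 7)))
  pre <- 1:110
  expect_equal(order(g_eff$study$panel$focal[pre]), order(pan$focal[pre]))
  expect_false(identical(g_eff$study$panel$focal[111:120],
                         pan$focal[111:120]))
})

test_that("import panels are overdispersed counts tied to references", {
  g <- generate_import_panel(scenario_config("imports", seed = 17,
                                             k_decoys = 2))
  pan <- g$study$panel
  foc <- pan$focal
  expect_true(all(foc >= 0 & foc == round(foc)))
  expect_equal(length(attr(pan, "ref_cols")), 6)  # 4 refs + 2 decoys
  # decoys are zero-dominated, real references are not
  expect_gt(mean(pan$decoy01 == 0), 0.5)
  expect_lt(mean(pan$ref01 == 0), 0.1)
  # focal scale matches the configured monthly import magnitude
  expect_gt(mean(foc), 2000)
  expect_lt(mean(foc), 30000)
})

test_that("visit series carry month effects, trend and realistic scale", {
  # near-noiseless series: adjacent December/January differ by the month
  # effect exactly on the log scale
  g0 <- generate_visits_series(scenario_config("visits", seed = 18,
                                               dispersion = 1e-9))
  pan0 <- g0$study$panel
  m <- as.POSIXlt(pan0$date)$mon + 1L
  dec <- log(pan0$focal[m == 12][1])
  jan_next <- log(pan0$focal[which(m == 12)[1] + 1])
  trend <- g0$truth$trend_fun
  t_dec <- to_decimal_date(pan0$date[m == 12][1])
  t_jan <- to_decimal_date(pan0$date[which(m == 12)[1] + 1])
  expect_equal(dec - jan_next,
               g0$truth$coefficients["month_Dec"] +
                 trend(t_dec) - trend(t_jan),
               ignore_attr = TRUE, tolerance = 1e-6)

  # realistic magnitude: annual sum within a factor of 2 of ~10.8M visits
  g <- generate_visits_series(scenario_config("visits", seed = 19))
  annual <- sum(g$study$panel$focal[1:12])
  expect_gt(annual, 10.8e6 / 2)
  expect_lt(annual, 10.8e6 * 2)
  expect_equal(nrow(g$study$panel), 132)
})

test_that("month-effect recovery from a typical visits run", {
  g <- generate_visits_series(scenario_config("visits", seed = 20))
  res <- evaluate_impact(g$study, model_spec("seasonal_trend"),
                         sampler_config(iterations = 1000, seed = 20))
  td <- tidy(res$samples)
  months <- td[grepl("^month_", td$term), ]
  truth <- g$truth$coefficients[months$term]
  covered <- months$conf.low <= truth & truth <= months$conf.high
  expect_gte(sum(covered), 8)
})

test_that("transient effects decay linearly to no effect", {
  ep <- transient_effect(2.1, 7)
  expect_equal(ep[1], 2.1)
  expect_equal(ep[7], 1)
  expect_equal(diff(ep), rep(diff(ep)[1], 6))
  expect_equal(cfimpact:::pad_profile(ep, 10), c(ep, rep(1, 3)))
  expect_equal(cfimpact:::pad_profile(ep, 4), ep[1:4])
})
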