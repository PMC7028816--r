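test_that("search design has intercept, mains and all pairwise interactions", {
  p6 <- toy_panel(n = 12, k = 6)
  d6 <- build_search_design(p6)
  expect_equal(ncol(d6$matrix), 1 + 6 + 15)
  expect_equal(d6$names[1], "intercept")
  expect_true(all(d6$matrix[, 1] == 1))

  p1 <- toy_panel(n = 8, k = 1)
  expect_equal(ncol(build_search_design(p1)$matrix), 2)

  # interaction columns are products of the named mains
  p3 <- toy_panel(n = 10, k = 3)
  d3 <- build_search_design(p3)
  expect_equal(ncol(d3$matrix), 1 + 3 + 3)
  expect_equal(d3$matrix[, "ref1:ref2"], d3$matrix[, "ref1"] * d3$matrix[, "ref2"])

  # constant references 0.5 give constant interactions 0.25
  pc <- toy_panel(n = 10, k = 3)
  for (nm in attr(pc, "ref_cols")) pc[[nm]] <- rep(0.5, 10)
  dc <- build_search_design(pc)
  expect_true(all(dc$matrix[, "ref2:ref3"] == 0.25))

  # column count law for several k
  for (k in c(2, 4, 5)) {
    expect_equal(ncol(build_search_design(toy_panel(n = 8, k = k))$matrix),
                 1 + k + k * (k - 1) / 2)
  }
})

test_that("import design is intercept plus main effects in reference order", {
  df <- tibble::tibble(
    date = seq(as.Date("2015-01-01"), by = "1 month", length.out = 6),
    focal = c(5L, 6L, 7L, 8L, 9L, 10L),
    b_ref = 1:6, a_ref = 6:1, c_ref = rep(2L, 6), d_ref = rep(3L, 6))
  p <- panel(df, frequency = "monthly", outcome_kind = "count")
  d <- build_import_design(p)
  expect_equal(d$names, c("intercept", "b_ref", "a_ref", "c_ref", "d_ref"))
  expect_equal(ncol(d$matrix), 5)
})

test_that("zero-dominated references are excluded with a message", {
  df <- tibble::tibble(
    date = seq(as.Date("2015-01-01"), by = "1 month", length.out = 24),
    focal = rep(10L, 24),
    good = rep(5L, 24),
    mostly0 = c(rep(0L, 20), rep(3L, 4)))
  p <- panel(df, frequency = "monthly", outcome_kind = "count")
  expect_message(p2 <- exclude_zero_dominated(p, 0.5), "mostly0")
  expect_identical(attr(p2, "ref_cols"), "good")
  expect_identical(attr(p2, "dropped_refs"), "mostly0")

  # threshold 1.0 keeps everything
  p3 <- exclude_zero_dominated(p, 1.0)
  expect_equal(length(attr(p3, "ref_cols")), 2)

  df$good <- rep(0L, 24)
  pall <- panel(df, frequency = "monthly", outcome_kind = "count")
  expect_error(suppressMessages(exclude_zero_dominated(pall, 0.5)),
               "all reference")
})

test_that("spline basis is a partition of unity and centres to the intercept", {
  t_std <- seq(-0.9, 0.9, length.out = 60)
  b <- spline_basis(t_std, num_basis = 10)
  raw <- spline_basis_eval(b, t_std, raw = TRUE)
  expect_equal(rowSums(raw), rep(1, 60), tolerance = 1e-12)
  expect_equal(dim(b$Z), c(60, 10))
  expect_equal(unname(colMeans(b$Z)), rep(0, 10), tolerance = 1e-12)
  # zero coefficients contribute exactly zero to the predictor
  expect_equal(drop(b$Z %*% rep(0, 10)), rep(0, 60))
  expect_error(spline_basis(t_std, num_basis = 3), "at least 4")
})

test_that("spline basis can represent a smooth quadratic", {
  t_std <- seq(-1, 1, length.out = 80)
  f <- 1.3 - 0.8 * t_std + 2 * t_std^2
  b <- spline_basis(t_std, num_basis = 10)
  X <- cbind(1, b$Z)
  fit <- lm.fit(X, f)
  expect_lt(max(abs(fit$residuals)), 0.01 * diff(range(f)))
})

test_that("spline evaluation extends linearly beyond the fitting range", {
  t_std <- seq(-1, 1, length.out = 50)
  b <- spline_basis(t_std, num_basis = 8)
  set.seed(3)
  coefs <- rnorm(8, 0, 0.5)
  g <- function(t) drop(spline_basis_eval(b, t) %*% coefs)
  # beyond the boundary the function is linear: equal second differences zero
  t_out <- c(1.1, 1.2, 1.3, 1.4)
  v <- g(t_out)
  expect_equal(diff(v, differences = 2), rep(0, 2), tolerance = 1e-10)
  # and continuous at the boundary with matching slope
  h <- 1e-6
  slope_in <- (g(1) - g(1 - h)) / h
  slope_out <- (g(1 + h) - g(1)) / h
  expect_equal(slope_in, slope_out, tolerance = 1e-3)
})

test_that("seasonal design uses January as the base month", {
  dates <- seq(as.Date("2010-01-01"), by = "1 month", length.out = 26)
  std <- standardize_time(dates)
  d <- build_seasonal_design(dates, std)
  expect_equal(d$names[1:3], c("intercept", "month_Feb", "month_Mar"))
  jan_rows <- which(as.POSIXlt(dates)$mon == 0)
  expect_true(all(d$matrix[jan_rows, -1] == 0))
  expect_equal(rowSums(d$matrix[-jan_rows, -1]), rep(1, 26 - length(jan_rows)))
  expect_equal(ncol(d$spline$Z), 10)
})
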