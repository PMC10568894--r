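test_that("local polynomial regression reproduces polynomials of its degree exactly", {
  x <- 1:96
  lin <- 3 + 2 * x
  for (span in c(0.17, 0.6)) {
    for (deg in 1:2) {
      fit <- loess_fit(lin, x, span = span, degree = deg)
      expect_lt(max(abs(fit$fitted - lin)), 1e-8)
    }
  }
  const <- loess_fit(rep(7, 60), span = 0.3)
  expect_lt(max(abs(const$fitted - 7)), 1e-8)
  expect_lt(max(const$se), 1e-8)
})

test_that("fitted values and standard errors match the hat-matrix reference", {
  fx <- utils::read.csv(toy_path("loess_fixture_96.csv"))
  for (span in c(0.17, 0.35)) {
    fit <- loess_fit(fx$y, fx$x, span = span, degree = 2)
    ref <- reference_local_regression(fx$y, fx$x, span = span, degree = 2)
    expect_lt(max(abs(fit$fitted - ref$fitted)), 1e-6)
    expect_lt(max(abs(fit$se - ref$se)), 1e-6)
  }
})

test_that("loess at full span, degree 1, equals ordinary least squares on trend data", {
  x <- 1:80
  y <- 5 - 1.3 * x
  fit <- loess_fit(y, x, span = 1, degree = 1)
  ols <- lm(y ~ x)
  expect_lt(max(abs(fit$fitted - fitted(ols))), 1e-6)
})

test_that("invalid smoothing inputs are rejected", {
  expect_error(loess_fit(c(1, NA, 3, 4, 5)), "NA")
  expect_error(loess_fit(1:3), "Too few")
  expect_error(loess_fit(1:50, span = 0), "span")
})

test_that("pointwise bands use the right quantile and widen with level", {
  fx <- utils::read.csv(toy_path("loess_fixture_96.csv"))
  fit <- loess_fit(fx$y, fx$x, span = 0.3)
  b999 <- pointwise_band(fit, 0.999)
  expect_equal(b999$ci_upper - fit$fitted, qnorm(0.9995) * fit$se)
  expect_equal(b999$ci_upper[10] - b999$ci_lower[10],
    2 * 3.29053 * fit$se[10],
    tolerance = 1e-5
  )
  b95 <- pointwise_band(fit, 0.95)
  expect_true(all(b999$ci_lower <= b95$ci_lower & b999$ci_upper >= b95$ci_upper))
  bt <- pointwise_band(fit, 0.999, quantile = "t")
  expect_true(all(bt$ci_upper >= b999$ci_upper)) # t quantile is wider
  expect_error(pointwise_band(fit, 1), "level")

  # se = 0 collapses the band onto the fit
  lin <- loess_fit(3 + 2 * (1:50), span = 0.5, degree = 1)
  bl <- pointwise_band(lin, 0.999)
  expect_lt(max(bl$ci_upper - bl$ci_lower), 1e-6)
})

test_that("the 99.9% band covers a known smooth curve almost everywhere", {
  x <- 1:105
  truth <- 200 + 30 * sin(2 * pi * x / 52)
  set.seed(505)
  coverage <- vapply(1:200, function(i) {
    y <- truth + rnorm(105, 0, 10)
    fit <- loess_fit(y, x, span = 0.17, degree = 2)
    band <- pointwise_band(fit, 0.999)
    mean(truth >= band$ci_lower & truth <= band$ci_upper)
  }, numeric(1))
  expect_gte(mean(coverage), 0.99)
})

test_that("mean deviation arithmetic, invariances and error cases", {
  expect_equal(mean_deviation(c(110, 90), c(100, 100)), 10)
  expect_equal(mean_deviation(1.5 * c(30, 50, 20), c(30, 50, 20)), 50)
  expect_equal(mean_deviation(c(4, 4), c(4, 4)), 0)
  # |.| prevents cancellation; rescaling invariance; zero iff identical
  o <- c(12, 30, 9, 40)
  p <- c(15, 22, 9, 41)
  expect_equal(mean_deviation(3 * o, 3 * p), mean_deviation(o, p))
  expect_gt(mean_deviation(o, p), 0)
  expect_error(mean_deviation(1:3, 1:4), "equal length")
  expect_error(mean_deviation(c(1, 2), c(0, 0)), "positive")
  expect_equal(expected_deviation(1.5, 1.0), 50)
  expect_equal(expected_deviation(1.0, 0.9), 100 / 9)
  expect_equal(expected_deviation(0.9, 0.9), 0)
  expect_error(expected_deviation(1, 0), "positive")
})

test_that("identical observed and forecast series produce a clean null comparison", {
  reg <- deterministic_registry(c("2020" = 1.0, "2021" = 1.0))
  pan <- build_dataset(reg$consultations, reg$population, cohort_spec(2019), "pan")
  pre <- build_dataset(reg$consultations, reg$population, cohort_spec(2017), "pre")
  fc <- fit_forecasts(pre, pan, "P74", n_boot = 200, seed = 2)
  obs <- slice_years(weekly_counts(pan, "P74"), 2020:2021)
  cmp <- compare_to_forecast(obs, fc$first, fc$second)
  expect_equal(cmp$mean_deviation_pct, 0)
  expect_true(all(cmp$table$flag == "none"))
  expect_equal(nrow(cmp$periods), 0)
  # window starts at 2020-W11 and runs through 2021-W52
  expect_equal(nrow(cmp$table), (53 - 10) + 52)
  expect_equal(cmp$table$iso_week[1], 11)
})

test_that("a sustained shift beyond the band is flagged as one above-period", {
  reg <- deterministic_registry(c("2020" = 1.0, "2021" = 1.0))
  pan <- build_dataset(reg$consultations, reg$population, cohort_spec(2019), "pan")
  pre <- build_dataset(reg$consultations, reg$population, cohort_spec(2017), "pre")
  fc <- fit_forecasts(pre, pan, "P74", n_boot = 200, seed = 2)
  obs <- slice_years(weekly_counts(pan, "P74"), 2020:2021)
  # shift weeks 20-30 of 2020 far above anything the band can absorb
  bump <- obs$iso_year == 2020 & obs$iso_week %in% 20:30
  obs$count <- obs$count + as.integer(bump) * as.integer(round(5 * max(obs$count)))
  cmp <- compare_to_forecast(obs, fc$first, fc$second)
  above <- cmp$periods[cmp$periods$direction == "above", ]
  expect_equal(nrow(above), 1)
  expect_true(above$start_iso_week <= 20 && above$end_iso_week >= 30)
  # flags and periods describe the same weeks
  flagged <- cmp$table$iso_week[cmp$table$flag != "none" & cmp$table$iso_year == 2020]
  expect_true(all(20:30 %in% flagged))
})

test_that("periods partition the flagged weeks into maximal runs", {
  flags <- c("none", "above", "above", "none", "below", "above", "above", "none")
  yr <- rep(2020L, 8)
  wk <- 11:18
  per <- significant_periods(flags, yr, wk)
  expect_equal(nrow(per), 3)
  expect_equal(per$direction, c("above", "below", "above"))
  expect_equal(per$start_iso_week, c(12L, 15L, 16L))
  expect_equal(sum(per$n_weeks), sum(flags != "none"))
})
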