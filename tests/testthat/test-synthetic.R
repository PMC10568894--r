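test_that("generation is deterministic given a seed", {
  a <- small_registry(seed = 8, n_patients = 400)
  b <- small_registry(seed = 8, n_patients = 400)
  expect_identical(
    flatten_consultations(a$consultations),
    flatten_consultations(b$consultations)
  )
  expect_identical(a$population, b$population)
  expect_identical(a$ground_truth$expected_counts, b$ground_truth$expected_counts)
  c <- small_registry(seed = 9, n_patients = 400)
  expect_false(identical(
    flatten_consultations(a$consultations),
    flatten_consultations(c$consultations)
  ))
})

test_that("gender split and age-group weights are recovered within binomial error", {
  reg <- generate_registry(synthetic_config(n_patients = 10000, seed = 13))
  frac_female <- mean(reg$population$gender == "female")
  expect_lt(abs(frac_female - 0.62), 3 * sqrt(0.62 * 0.38 / 10000))

  ds <- build_dataset(reg$consultations, reg$population, cohort_spec(2019), "pan")
  sm <- dataset_summary(ds)
  expect_lt(abs(sm$patients$pct_women - 62), 3) # cohort-level recovery
})

test_that("consultation record fields pass the registry validators", {
  reg <- small_registry(seed = 2, n_patients = 300)
  expect_true(all(vapply(
    reg$consultations$diagnosis_codes,
    function(cc) length(cc) >= 1 && all(grepl("^[A-Z][0-9]{2}$", cc)), logical(1)
  )))
  expect_true(all(reg$consultations$contact_type %in% contact_types()))
  expect_true(all(reg$population$birth_year >= 1900))
})

test_that("without shared seasonality or frailty the between-year correlation vanishes", {
  reg <- generate_registry(synthetic_config(
    n_patients = 4000, seed = 17,
    season_amplitude = 0,
    dip_weeks = tibble::tibble(week = integer(), factor = numeric()),
    frailty_shape = 1e6, week_affinity = 0
  ))
  pre <- build_dataset(reg$consultations, reg$population, cohort_spec(2017), "pre")
  s <- weekly_counts(pre, "P76")
  pair <- align_weeks(slice_years(s, 2017), slice_years(s, 2018))
  expect_lt(abs(cor(pair$x, pair$y)), 0.45) # ~N(0, 1/sqrt(51)) under independence
})

test_that("stronger patient heterogeneity raises the between-year correlation", {
  r_for_shape <- function(shape) {
    rs <- vapply(c(41, 42, 43), function(sd) {
      reg <- generate_registry(synthetic_config(
        n_patients = 2500, seed = sd,
        season_amplitude = 0,
        dip_weeks = tibble::tibble(week = integer(), factor = numeric()),
        frailty_shape = shape, persistence = 1, week_affinity = 0.8
      ))
      pre <- build_dataset(reg$consultations, reg$population, cohort_spec(2017), "pre")
      s <- weekly_counts(pre, "P76")
      pair <- align_weeks(slice_years(s, 2017), slice_years(s, 2018))
      cor(pair$x, pair$y)
    }, numeric(1))
    mean(rs)
  }
  expect_gt(r_for_shape(0.3), r_for_shape(5))
})

test_that("the implied-correlation approximation tracks the realised correlation", {
  reg <- small_registry(seed = 37, n_patients = 5000)
  pre <- build_dataset(reg$consultations, reg$population, cohort_spec(2017), "pre")
  s <- weekly_counts(pre, "P76")
  pair <- align_weeks(slice_years(s, 2017), slice_years(s, 2018))
  realized <- cor(pair$x, pair$y)
  implied <- implied_correlation(reg$ground_truth, "P76", 2017, 2018)
  expect_lt(abs(realized - implied), 0.1)
})

test_that("scheduled effects scale realised counts by the multiplier", {
  eff <- tibble::tibble(
    code = "P82", start_year = 2020L, start_week = 11L,
    end_year = 2021L, end_week = 52L, multiplier = 2
  )
  base <- generate_registry(synthetic_config(n_patients = 4000, seed = 77))
  shocked <- generate_registry(synthetic_config(
    n_patients = 4000, seed = 77,
    effect_schedule = eff
  ))
  gt0 <- base$ground_truth$expected_counts
  gt1 <- shocked$ground_truth$expected_counts
  in_window <- gt0$code == "P82" & (gt0$iso_year == 2021 |
    (gt0$iso_year == 2020 & gt0$iso_week >= 11))
  expect_equal(gt1$expected[in_window], 2 * gt0$expected[in_window])
  out_window <- gt0$code == "P82" & gt0$iso_year == 2019
  expect_equal(gt1$expected[out_window], gt0$expected[out_window])

  # realised counts follow suit (Poisson tolerance)
  count_in <- function(reg) {
    ds <- build_dataset(reg$consultations, reg$population, cohort_spec(2019), "pan")
    s <- weekly_counts(ds, "P82")
    sum(s$count[s$iso_year == 2021])
  }
  expect_lt(abs(count_in(shocked) / count_in(base) - 2), 0.15)
})

test_that("registration loss drops the stated share of final-December consultations", {
  full <- generate_registry(synthetic_config(n_patients = 3000, seed = 55))
  lossy <- generate_registry(synthetic_config(
    n_patients = 3000, seed = 55,
    registration_loss = 0.5
  ))
  dec <- function(reg) sum(format(reg$consultations$date, "%Y-%m") == "2021-12")
  expect_lt(abs(dec(lossy) / dec(full) - 0.5), 0.1)
  other <- function(reg) sum(format(reg$consultations$date, "%Y-%m") != "2021-12")
  expect_equal(other(lossy), other(full))
})

test_that("cohort-conditional expected counts track realised cohort totals", {
  reg <- generate_registry(synthetic_config(n_patients = 8000, seed = 91))
  pan <- build_dataset(reg$consultations, reg$population, cohort_spec(2019), "pan")
  s <- weekly_counts(pan, "P76")
  gt <- reg$ground_truth$expected_cohort_counts
  gt <- gt[gt$inclusion_year == 2019 & gt$code == "P76", ]
  for (y in 2019:2021) {
    realized <- sum(s$count[s$iso_year == y])
    expected <- sum(gt$expected[gt$iso_year == y])
    expect_lt(abs(realized / expected - 1), 0.05)
  }
})

test_that("deterministic mode builds exact copies and exact multiples", {
  reg <- deterministic_registry(c("2020" = 1.5, "2021" = 0.8))
  pan <- build_dataset(reg$consultations, reg$population, cohort_spec(2019), "pan")
  pre <- build_dataset(reg$consultations, reg$population, cohort_spec(2017), "pre")
  s_pre <- weekly_counts(pre, "P79")
  y17 <- slice_years(s_pre, 2017)$count
  expect_equal(slice_years(s_pre, 2018)$count, y17)
  expect_equal(slice_years(s_pre, 2019)$count, y17)
  expect_false(sd(y17) == 0)

  s_pan <- weekly_counts(pan, "P79")
  y19 <- slice_years(s_pan, 2019)$count
  y20 <- slice_years(s_pan, 2020)$count
  expect_equal(y20[1:52], as.integer(round(1.5 * y19)))
  expect_equal(y20[53], as.integer(round(1.5 * y19[52])))
  expect_equal(slice_years(s_pan, 2021)$count, as.integer(round(0.8 * y19)))
})

test_that("infeasible configurations are refused", {
  expect_error(synthetic_config(n_patients = 1e8), "Infeasible")
  expect_error(synthetic_config(gender_split = 1.4))
  expect_error(synthetic_config(age_group_weights = c(0.5, 0.5, 0.5)))
})
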