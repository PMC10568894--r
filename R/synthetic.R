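#' Configuration for the synthetic registry generator
#'
#' Describes a synthetic consultation registry with the statistical
#' structure the analysis assumes: per-diagnosis weekly consultation
#' intensities with seasonal structure and holiday dips, patient-level
#' gamma frailty with year-to-year persistence (producing positive
#' between-year correlation of weekly totals), symptom-code mixing
#' (P03/P01 alongside the disorder codes), gender/age-group structure, and
#' configurable multiplicative pandemic shocks per diagnosis and period.
#'
#' Patient `i` with assigned diagnosis `d` generates consultations in week
#' `w` of year `y` from a Poisson process with intensity
#' `rate_d * u_{iy} * s_w * (1 + b * cos(2*pi*(w - phi_{iy})/52)) * m_d(y, w)`
#' where `s_w` is the shared seasonal/holiday profile, `u_{iy}` a
#' Gamma(shape, shape) frailty, `phi_{iy}` a patient-specific timing phase,
#' `b` the within-year timing affinity, and `m_d` the scheduled effect
#' multiplier. Each year, a patient keeps their frailty and phase with
#' probability `persistence`, otherwise both are redrawn — correlation
#' between years therefore decays with lag.
#'
#' The default regime depicts fairly regular attenders (annual per-patient
#' disorder-code intensity of roughly 2.5-5 consultations) with highly
#' persistent propensities. This keeps the selection effect of requiring
#' one inclusion-year consultation mild — the follow-year/inclusion-year
#' level ratio is `E[u(1 - exp(-mu*u))]/E[u]`, about 0.98 under the
#' defaults — so the correlation-scaled forecast's premise (follow-year
#' counts at most at the inclusion-year level, with the ratio carried by
#' the between-year correlation) holds in the synthetic world. Rare
#' attenders would induce a stronger regression-to-the-mean drop than the
#' forecast model can represent; see the methods vignette.
#'
#' @param n_patients Number of patients (default 20000).
#' @param years Calendar/ISO years covered (default 2017:2021).
#' @param gender_split Fraction female (default 0.62).
#' @param age_group_weights Probabilities of the three age groups 18-24,
#'   25-39, 40-65 (must sum to 1).
#' @param age_reference_year Year at which ages are anchored (default 2019).
#' @param diagnosis_params Tibble with one row per disorder code: `code`,
#'   `share` (patient assignment probability), `weekly_rate` (baseline
#'   per-patient weekly intensity), `symptom_code` (companion symptom code
#'   or NA), `symptom_prob` (probability a consultation is coded with the
#'   symptom code instead of the disorder code), `multi_code_prob`
#'   (probability a disorder consultation also carries the symptom code).
#' @param season_amplitude,season_phase Seasonal modulation
#'   `1 + a * cos(2*pi*(w - phase)/52)`; default amplitude 0.25, peak near
#'   week 4 (late winter).
#' @param dip_weeks Tibble `week`, `factor`: multiplicative holiday dips
#'   (defaults: summer weeks 26-32 at 0.55, Christmas weeks 51-53 at 0.5,
#'   an Easter-like dip at week 15 at 0.75).
#' @param frailty_shape Gamma shape `k` of the mean-1 patient frailty
#'   (smaller = more heterogeneity; default 2).
#' @param persistence Probability a patient's frailty/phase carries over to
#'   the next year (default 0.97).
#' @param week_affinity Amplitude `b` of the patient-specific within-year
#'   timing profile (default 0.4).
#' @param effect_schedule Tibble `code`, `start_year`, `start_week`,
#'   `end_year`, `end_week`, `multiplier`: multiplicative pandemic shocks.
#'   Default: none.
#' @param registration_loss Fraction of consultations in December of the
#'   final year dropped, emulating late registration; default 0.
#' @param seed Integer RNG seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 20000L,
                             years = 2017:2021,
                             gender_split = 0.62,
                             age_group_weights = c(0.15, 0.33, 0.52),
                             age_reference_year = 2019L,
                             diagnosis_params = default_diagnosis_params(),
                             season_amplitude = 0.25,
                             season_phase = 4,
                             dip_weeks = default_dip_weeks(),
                             frailty_shape = 2,
                             persistence = 0.97,
                             week_affinity = 0.4,
                             effect_schedule = empty_effect_schedule(),
                             registration_loss = 0,
                             seed = 1L) {
  stopifnot(
    n_patients >= 1, length(years) >= 2, all(diff(years) == 1),
    gender_split >= 0, gender_split <= 1,
    length(age_group_weights) == 3, all(age_group_weights >= 0),
    abs(sum(age_group_weights) - 1) < 1e-8,
    season_amplitude >= 0, season_amplitude < 1,
    all(dip_weeks$factor > 0),
    frailty_shape > 0, persistence >= 0, persistence <= 1,
    week_affinity >= 0, week_affinity < 1,
    all(diagnosis_params$weekly_rate > 0), all(diagnosis_params$share > 0),
    all(effect_schedule$multiplier > 0),
    registration_loss >= 0, registration_loss <= 1
  )
  # overflow guard: expected total consultations
  expected_total <- n_patients * sum(diagnosis_params$share * diagnosis_params$weekly_rate) *
    52 * length(years) * max(1, max(c(1, effect_schedule$multiplier)))
  if (expected_total > 5e7) {
    stop("Infeasible config: expected ~", format(expected_total, big.mark = ","),
      " consultations.",
      call. = FALSE
    )
  }
  structure(
    list(
      n_patients = as.integer(n_patients), years = as.integer(years),
      gender_split = gender_split, age_group_weights = age_group_weights,
      age_reference_year = as.integer(age_reference_year),
      diagnosis_params = diagnosis_params,
      season_amplitude = season_amplitude, season_phase = season_phase,
      dip_weeks = dip_weeks, frailty_shape = frailty_shape,
      persistence = persistence, week_affinity = week_affinity,
      effect_schedule = effect_schedule, registration_loss = registration_loss,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' @rdname synthetic_config
#' @export
default_diagnosis_params <- function() {
  tibble::tibble(
    code = c("P76", "P74", "P79", "P82", "P86"),
    share = c(0.34, 0.34, 0.13, 0.11, 0.08),
    weekly_rate = c(0.12, 0.12, 0.09, 0.09, 0.06),
    symptom_code = c("P03", "P01", NA, NA, NA),
    symptom_prob = c(0.25, 0.25, 0, 0, 0),
    multi_code_prob = c(0.05, 0.05, 0, 0, 0)
  )
}

#' @rdname synthetic_config
#' @export
default_dip_weeks <- function() {
  tibble::tibble(
    week = c(26:32, 51:53, 15),
    factor = c(rep(0.55, 7), rep(0.5, 3), 0.75)
  )
}

#' @rdname synthetic_config
#' @export
empty_effect_schedule <- function() {
  tibble::tibble(
    code = character(), start_year = integer(), start_week = integer(),
    end_year = integer(), end_week = integer(), multiplier = numeric()
  )
}

# Shared weekly profile s_w for one ISO year.
seasonal_profile <- function(config, n_weeks) {
  w <- seq_len(n_weeks)
  s <- 1 + config$season_amplitude * cos(2 * pi * (w - config$season_phase) / 52)
  idx <- match(w, config$dip_weeks$week)
  s <- s * ifelse(is.na(idx), 1, config$dip_weeks$factor[idx])
  s
}

# Effect multiplier vector for one code and ISO year.
effect_multiplier <- function(schedule, code, year, n_weeks) {
  m <- rep(1, n_weeks)
  rows <- schedule[schedule$code == code, , drop = FALSE]
  if (nrow(rows) == 0) {
    return(m)
  }
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    if (year < r$start_year || year > r$end_year) next
    from <- if (year == r$start_year) r$start_week else 1L
    to <- if (year == r$end_year) r$end_week else n_weeks
    to <- min(to, n_weeks)
    if (from <= to) m[from:to] <- m[from:to] * r$multiplier
  }
  m
}

#' Generate a synthetic consultation registry
#'
#' Draws a population and a consultation-level extract under the model
#' described in [synthetic_config()], together with the ground truth
#' needed to compute expected values of downstream statistics: the
#' realised per-week expected disorder-coded counts per diagnosis, and the
#' injected effect schedule. Deterministic given the config seed; written
#' files pass the registry readers' validation.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory; if given, writes
#'   `population.csv`, `consultations.csv` and `ground_truth.json` there.
#' @return List with `population` (tibble), `consultations` (validated
#'   record tibble as from [read_consultations()]), `ground_truth` (list:
#'   `expected_counts` tibble `code, iso_year, iso_week, expected` over all
#'   patients; `expected_cohort_counts` additionally keyed by
#'   `inclusion_year`, giving expected counts among the members of that
#'   year's cohort; `effect_schedule`, `frailty_shape`, `persistence`),
#'   and `paths` (if `dir` was given).
#' @export
generate_registry <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_registry_impl(config, dir))
}

generate_registry_impl <- function(config, dir) {
  n <- config$n_patients
  years <- config$years
  dp <- config$diagnosis_params

  # population ---------------------------------------------------------------
  gender <- ifelse(stats::runif(n) < config$gender_split, "female", "male")
  group <- sample.int(3, n, replace = TRUE, prob = config$age_group_weights)
  lo <- c(18L, 25L, 40L)[group]
  hi <- c(24L, 39L, 65L)[group]
  age <- lo + floor(stats::runif(n) * (hi - lo + 1L))
  population <- tibble::tibble(
    patient_id = sprintf("S%06d", seq_len(n)),
    gender = gender,
    birth_year = config$age_reference_year - as.integer(age)
  )

  # latent patient state ------------------------------------------------------
  diag_idx <- sample.int(nrow(dp), n, replace = TRUE, prob = dp$share)
  n_years <- length(years)
  u <- matrix(0, n, n_years)
  phi <- matrix(0, n, n_years)
  u[, 1] <- stats::rgamma(n, shape = config$frailty_shape, rate = config$frailty_shape)
  phi[, 1] <- stats::runif(n, 0, 52)
  if (n_years > 1) {
    for (t in 2:n_years) {
      keep <- stats::runif(n) < config$persistence
      u[, t] <- ifelse(keep, u[, t - 1],
        stats::rgamma(n, shape = config$frailty_shape, rate = config$frailty_shape)
      )
      phi[, t] <- ifelse(keep, phi[, t - 1], stats::runif(n, 0, 52))
    }
  }

  # weekly counts and consultation rows --------------------------------------
  # Candidate inclusion years (pre-pandemic and pandemic datasets): the
  # cohort-conditional expected counts need each patient's total intensity
  # in those years and the age window at those years.
  incl_years <- intersect(c(years[1], years[min(3, n_years)]), years)
  lambda_incl <- matrix(0, n, length(incl_years),
    dimnames = list(NULL, as.character(incl_years))
  )
  pieces <- vector("list", n_years * nrow(dp))
  expected <- vector("list", n_years * nrow(dp))
  expected_cohort <- list()
  k <- 0L
  for (t in seq_len(n_years)) {
    y <- years[t]
    n_weeks <- iso_weeks_in_year(y)
    s <- seasonal_profile(config, n_weeks)
    mondays <- iso_week_monday(y, seq_len(n_weeks))
    for (d in seq_len(nrow(dp))) {
      pats <- which(diag_idx == d)
      if (length(pats) == 0) next
      eff <- effect_multiplier(config$effect_schedule, dp$code[d], y, n_weeks)
      wk <- seq_len(n_weeks)
      # rates: patients x weeks
      timing <- 1 + config$week_affinity *
        cos(2 * pi * outer(-phi[pats, t], wk, `+`) / 52)
      rates <- dp$weekly_rate[d] * u[pats, t] * timing *
        matrix(s * eff, length(pats), n_weeks, byrow = TRUE)
      counts <- matrix(stats::rpois(length(rates), rates), nrow = length(pats))
      nz <- which(counts > 0, arr.ind = TRUE)
      k <- k + 1L
      expected[[k]] <- tibble::tibble(
        code = dp$code[d], iso_year = y, iso_week = wk,
        expected = colSums(rates) * (1 - dp$symptom_prob[d])
      )
      if (as.character(y) %in% colnames(lambda_incl)) {
        lambda_incl[pats, as.character(y)] <- rowSums(rates)
      }
      # Expected disorder-coded counts among cohort members. For the
      # inclusion year itself E[D * 1(total >= 1)] = E[D] (zero-count
      # patients contribute nothing); for follow years each patient's rate
      # is weighted by the membership probability 1 - exp(-Lambda_incl).
      for (iy in incl_years) {
        if (y < iy) next
        age_ok <- {
          a <- iy - population$birth_year[pats]
          a >= 18 & a <= 65
        }
        w_pat <- if (y == iy) {
          as.numeric(age_ok)
        } else {
          age_ok * (1 - exp(-lambda_incl[pats, as.character(iy)]))
        }
        expected_cohort[[length(expected_cohort) + 1L]] <- tibble::tibble(
          inclusion_year = iy, code = dp$code[d], iso_year = y, iso_week = wk,
          expected = as.numeric(crossprod(w_pat, rates)) * (1 - dp$symptom_prob[d])
        )
      }
      if (nrow(nz) == 0) next
      reps <- counts[nz]
      pieces[[k]] <- tibble::tibble(
        patient_idx = rep(pats[nz[, 1]], reps),
        monday = rep(mondays[nz[, 2]], reps),
        diag = d
      )
    }
  }
  cons <- dplyr::bind_rows(pieces)
  m <- nrow(cons)
  date <- cons$monday + sample.int(7, m, replace = TRUE) - 1L

  # diagnosis coding: symptom-only vs disorder (+ optional symptom companion)
  sp <- dp$symptom_prob[cons$diag]
  mc <- dp$multi_code_prob[cons$diag]
  symptom_only <- stats::runif(m) < sp
  add_symptom <- !symptom_only & stats::runif(m) < mc
  disorder <- dp$code[cons$diag]
  symptom <- dp$symptom_code[cons$diag]
  codes <- vector("list", m)
  codes[symptom_only] <- as.list(symptom[symptom_only])
  codes[add_symptom] <- mapply(c, disorder[add_symptom], symptom[add_symptom],
    SIMPLIFY = FALSE, USE.NAMES = FALSE
  )
  plain <- !symptom_only & !add_symptom
  codes[plain] <- as.list(disorder[plain])

  ct <- sample(contact_types(), m,
    replace = TRUE,
    prob = c(0.55, 0.05, 0.10, 0.07, 0.15, 0.03, 0.03, 0.02)
  )

  consultations <- tibble::tibble(
    patient_id = population$patient_id[cons$patient_idx],
    date = date, diagnosis_codes = codes, contact_type = ct
  )

  if (config$registration_loss > 0) {
    dec <- format(consultations$date, "%Y-%m") == sprintf("%d-12", max(years))
    drop <- dec & stats::runif(m) < config$registration_loss
    consultations <- consultations[!drop, , drop = FALSE]
  }
  consultations <- consultations[order(consultations$date, consultations$patient_id), ]

  ground_truth <- list(
    expected_counts = dplyr::bind_rows(expected),
    expected_cohort_counts = dplyr::bind_rows(expected_cohort),
    effect_schedule = config$effect_schedule,
    frailty_shape = config$frailty_shape,
    persistence = config$persistence,
    seed = config$seed
  )

  out <- list(
    population = population, consultations = consultations,
    ground_truth = ground_truth
  )
  if (!is.null(dir)) out$paths <- write_registry(out, dir)
  out
}

# Write a generated registry in the documented file dialect.
write_registry <- function(registry, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    population = file.path(dir, "population.csv"),
    consultations = file.path(dir, "consultations.csv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  readr::write_csv(registry$population, paths$population)
  flat <- registry$consultations
  flat$diagnosis_codes <- vapply(
    flat$diagnosis_codes, paste, character(1),
    collapse = ";"
  )
  flat$date <- format(flat$date, "%Y-%m-%d")
  readr::write_csv(flat, paths$consultations)
  jsonlite::write_json(
    registry$ground_truth, paths$ground_truth,
    auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null"
  )
  invisible(paths)
}

#' Between-year correlation implied by a generated registry's ground truth
#'
#' Approximates the attainable Pearson correlation between two years'
#' weekly disorder-coded totals for a diagnosis: the realised expected
#' weekly profiles supply the shared signal, and Poisson noise (variance
#' equal to the weekly mean) attenuates it:
#' `cov_w(E_a, E_b) / sqrt((var_w(E_a) + mean_w(E_a)) * (var_w(E_b) + mean_w(E_b)))`.
#'
#' @param ground_truth The `ground_truth` element from
#'   [generate_registry()].
#' @param code Diagnosis code.
#' @param year_a,year_b The two ISO years.
#' @return Scalar approximate correlation.
#' @export
implied_correlation <- function(ground_truth, code, year_a, year_b) {
  ec <- ground_truth$expected_counts
  ea <- ec$expected[ec$code == code & ec$iso_year == year_a]
  eb <- ec$expected[ec$code == code & ec$iso_year == year_b]
  n <- min(length(ea), length(eb))
  ea <- ea[seq_len(n)]
  eb <- eb[seq_len(n)]
  num <- stats::cov(ea, eb)
  num / sqrt((stats::var(ea) + mean(ea)) * (stats::var(eb) + mean(eb)))
}

#' Deterministic registry with exact year-to-year ratios
#'
#' Exact-oracle mode for end-to-end validation: weekly counts per diagnosis
#' follow a fixed non-constant base profile (multiples of 10); the
#' pre-pandemic follow years (2018, 2019) are exact copies of the 2017
#' inclusion-year profile — forcing every bootstrap correlation to equal 1
#' exactly — and the pandemic years are exact week-wise multiples of the
#' 2019 profile (2020's ISO week 53 reuses the week-52 value). With ratios
#' that keep `ratio * base` integral (e.g. 1.0, 1.2, 1.5 on multiples of
#' 10), the pipeline's mean deviation equals `100 * (ratio - 1)` exactly.
#'
#' @param ratios Named numeric: multiplier per pandemic year, e.g.
#'   `c("2020" = 1.5, "2021" = 1.5)`.
#' @param years Five consecutive years (default 2017:2021): inclusion,
#'   two pre-pandemic follow copies, two pandemic multiple years.
#' @param pool_size Patients per diagnosis (default 100); consultations are
#'   assigned round-robin so every patient consults in every year.
#' @param dir Optional output directory (same files as
#'   [generate_registry()]).
#' @return Same shape as [generate_registry()]; `ground_truth` holds the
#'   base profile and the ratios.
#' @export
deterministic_registry <- function(ratios = c("2020" = 1.0, "2021" = 1.0),
                                   years = 2017:2021, pool_size = 100L,
                                   dir = NULL) {
  stopifnot(length(years) == 5, all(ratios > 0))
  codes <- default_diagnosis_params()$code
  base <- function(w) 10L * (3L + as.integer(round(2 * cos(2 * pi * (w - 4) / 52))))
  base_counts <- base(1:52)

  pieces <- list()
  pops <- list()
  for (d in seq_along(codes)) {
    ids <- sprintf("D%d_P%03d", d, seq_len(pool_size))
    pops[[d]] <- tibble::tibble(
      patient_id = ids,
      gender = rep(c("female", "male"), c(62, 38) * pool_size / 100)[seq_len(pool_size)],
      birth_year = 1960L + (seq_len(pool_size) - 1L) %% 40L # ages 19-59 at 2019
    )
    for (y in years) {
      n_weeks <- iso_weeks_in_year(y)
      ratio <- if (as.character(y) %in% names(ratios)) ratios[[as.character(y)]] else 1
      counts <- as.integer(round(ratio * base_counts[pmin(1:n_weeks, 52)]))
      week <- rep(seq_len(n_weeks), counts)
      j <- seq_along(week)
      pieces[[length(pieces) + 1L]] <- tibble::tibble(
        patient_id = ids[(j - 1L) %% pool_size + 1L],
        date = iso_week_monday(y, week) + (j %% 5L),
        diagnosis_codes = as.list(rep(codes[d], length(week))),
        contact_type = rep(contact_types()[(d - 1L) %% 8L + 1L], length(week))
      )
    }
  }
  consultations <- dplyr::bind_rows(pieces)
  consultations <- consultations[order(consultations$date, consultations$patient_id), ]
  out <- list(
    population = dplyr::bind_rows(pops),
    consultations = consultations,
    ground_truth = list(
      base_counts = base_counts, ratios = as.list(ratios),
      effect_schedule = empty_effect_schedule()
    )
  )
  if (!is.null(dir)) out$paths <- write_registry(out, dir)
  out
}

#' Expected mean deviation under a constant multiplicative effect
#'
#' Analytic oracle: when observed counts are `m` times the no-effect level
#' and the forecast is `r_mean` times that level, the mean deviation is
#' `100 * |m - r_mean| / r_mean`. Note a no-effect scenario (`m = 1`) still
#' yields a positive deviation whenever `r_mean < 1` — a structural
#' property of the correlation-scaled forecast.
#'
#' @param multiplier The constant effect multiplier `m` over the window.
#' @param r_mean The mean correlation used for the forecast; must be > 0.
#' @return Expected mean deviation, in percent.
#' @examples
#' expected_deviation(1.5, 1.0) # 50
#' @export
expected_deviation <- function(multiplier, r_mean) {
  if (r_mean <= 0) stop("`r_mean` must be positive.", call. = FALSE)
  100 * abs(multiplier - r_mean) / r_mean
}

#' Exact expected mean deviation from a generated registry's ground truth
#'
#' Computes the expected value of the pipeline's mean-deviation statistic
#' for one diagnosis from the cohort-conditional expected weekly counts:
#' expected observed counts are the follow-year cohort expectations;
#' expected predicted counts are `r x` the inclusion-year cohort
#' expectations, paired by ISO week with the final source week carried
#' into a 53rd target week. Unlike the closed form [expected_deviation()],
#' this accounts for the mild cohort-selection deflation of follow-year
#' levels.
#'
#' @param ground_truth `ground_truth` from [generate_registry()] (must
#'   contain `expected_cohort_counts`).
#' @param code Diagnosis code.
#' @param inclusion_year Cohort inclusion year (e.g. 2019).
#' @param r_first,r_second The two forecast scaling correlations.
#' @param window_start `c(iso_year, iso_week)` analysis window start.
#' @return Expected mean deviation, in percent.
#' @export
expected_deviation_from_truth <- function(ground_truth, code, inclusion_year,
                                          r_first, r_second,
                                          window_start = c(2020L, 11L)) {
  ec <- ground_truth$expected_cohort_counts
  ec <- ec[ec$inclusion_year == inclusion_year & ec$code == code, ]
  if (nrow(ec) == 0) stop("No cohort-conditional ground truth for this code/year.", call. = FALSE)
  src <- ec$expected[ec$iso_year == inclusion_year]
  obs <- numeric(0)
  pred <- numeric(0)
  years <- sort(setdiff(unique(ec$iso_year), inclusion_year))[1:2]
  for (j in 1:2) {
    e <- ec[ec$iso_year == years[j], ]
    e <- e$expected[order(e$iso_week)]
    p <- c(r_first, r_second)[j] * src[pmin(seq_along(e), length(src))]
    wk <- seq_along(e)
    keep <- years[j] > window_start[1] |
      (years[j] == window_start[1] & wk >= window_start[2])
    obs <- c(obs, e[keep])
    pred <- c(pred, p[keep])
  }
  mean_deviation(obs, pred)
}
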