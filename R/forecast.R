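#' Bootstrap estimate of the mean Pearson correlation between two years
#'
#' Pairs bootstrap over weekly totals: week-index pairs `(x_w, y_w)` are
#' resampled with replacement `n_boot` times; the Pearson correlation is
#' computed on every non-degenerate resample (both resampled vectors
#' non-constant) and averaged. With only one pre-pandemic observation
#' period available, this simulates a sampling distribution of
#' between-year correlations; the resulting mean is treated as a fixed
#' scaling constant downstream.
#'
#' Degenerate resamples are excluded from the average rather than redrawn;
#' `n_valid` reports how many were used.
#'
#' @param x,y Equal-length weekly count vectors (length at least 3), e.g.
#'   from [align_weeks()]. Both must be non-constant.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Optional integer seed; given the same seed the estimate is
#'   reproducible.
#' @param year_pair Optional integer pair recording which years were
#'   correlated (metadata only).
#' @return An object of class `correlation_estimate`: list with `r_mean`,
#'   `r_sd` (bootstrap standard deviation), `n_boot`, `n_valid`, `seed`,
#'   `year_pair`.
#' @examples
#' est <- bootstrap_mean_correlation(1:52, (1:52) + rnorm(52), seed = 1)
#' est$r_mean
#' @export
bootstrap_mean_correlation <- function(x, y, n_boot = 10000L, seed = NULL,
                                       year_pair = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length.", call. = FALSE)
  if (n < 3) stop("Need at least 3 week pairs.", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("NA in input vectors.", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Correlation undefined: a constant weekly series.", call. = FALSE)
  }

  draw <- function() {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    X <- matrix(x[idx], nrow = n)
    Y <- matrix(y[idx], nrow = n)
    mx <- colMeans(X)
    my <- colMeans(Y)
    Xc <- sweep(X, 2, mx)
    Yc <- sweep(Y, 2, my)
    sxx <- colSums(Xc^2)
    syy <- colSums(Yc^2)
    sxy <- colSums(Xc * Yc)
    valid <- sxx > 0 & syy > 0
    list(r = sxy[valid] / sqrt(sxx[valid] * syy[valid]), n_valid = sum(valid))
  }
  res <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (res$n_valid == 0) stop("All bootstrap resamples were degenerate.", call. = FALSE)

  structure(
    list(
      r_mean = mean(res$r),
      r_sd = if (res$n_valid > 1) stats::sd(res$r) else 0,
      n_boot = as.integer(n_boot), n_valid = as.integer(res$n_valid),
      seed = seed, year_pair = year_pair
    ),
    class = "correlation_estimate"
  )
}

#' @export
print.correlation_estimate <- function(x, ...) {
  cat(sprintf(
    "<correlation_estimate> r_mean = %.4f (sd %.4f), %d/%d valid resamples%s\n",
    x$r_mean, x$r_sd, x$n_valid, x$n_boot,
    if (!is.null(x$year_pair)) paste0(", years ", paste(x$year_pair, collapse = "-")) else ""
  ))
  invisible(x)
}

#' Patient-level bootstrap of the mean between-year correlation
#'
#' Sensitivity-analysis alternative to the week-pairs bootstrap: patients
#' (not weeks) are resampled with replacement, the two years' weekly total
#' vectors are rebuilt from each patient resample, and the Pearson
#' correlation between them is averaged over resamples.
#'
#' @param ds An `analysis_dataset`.
#' @param diagnosis An analysis code.
#' @param year_x,year_y The two ISO years to correlate.
#' @param strat A [stratum()].
#' @inheritParams bootstrap_mean_correlation
#' @return A `correlation_estimate`.
#' @export
bootstrap_mean_correlation_patients <- function(ds, diagnosis, year_x, year_y,
                                                strat = stratum("overall"),
                                                n_boot = 10000L, seed = NULL) {
  series <- weekly_counts(ds, diagnosis, strat)
  members <- intersect(
    stratum_members(ds, strat),
    unique(ds$consultations$patient_id)
  )
  rows <- ds$code_flags[, toupper(diagnosis)] &
    ds$consultations$patient_id %in% members
  cons <- ds$consultations[rows, ]
  yr <- iso_year(cons$date)
  wk <- iso_week(cons$date)
  keep <- yr %in% c(year_x, year_y)
  cons <- cons[keep, ]
  yr <- yr[keep]
  wk <- wk[keep]
  pid <- match(cons$patient_id, members)
  n_pat <- length(members)
  wx <- min(iso_weeks_in_year(c(year_x, year_y)))

  # per-patient weekly matrices (patients x weeks)
  mk <- function(target_year) {
    sel <- yr == target_year & wk <= wx
    m <- matrix(0L, nrow = n_pat, ncol = wx)
    if (any(sel)) {
      tab <- table(factor(pid[sel], levels = seq_len(n_pat)), factor(wk[sel], levels = seq_len(wx)))
      m <- matrix(as.integer(tab), nrow = n_pat)
    }
    m
  }
  mx <- mk(year_x)
  my <- mk(year_y)

  draw <- function() {
    r <- numeric(n_boot)
    ok <- logical(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n_pat, n_pat, replace = TRUE)
      xs <- colSums(mx[idx, , drop = FALSE])
      ys <- colSums(my[idx, , drop = FALSE])
      if (stats::sd(xs) > 0 && stats::sd(ys) > 0) {
        r[b] <- stats::cor(xs, ys)
        ok[b] <- TRUE
      }
    }
    list(r = r[ok], n_valid = sum(ok))
  }
  res <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (res$n_valid == 0) stop("All bootstrap resamples were degenerate.", call. = FALSE)
  structure(
    list(
      r_mean = mean(res$r), r_sd = if (res$n_valid > 1) stats::sd(res$r) else 0,
      n_boot = as.integer(n_boot), n_valid = as.integer(res$n_valid),
      seed = seed, year_pair = c(year_x, year_y)
    ),
    class = "correlation_estimate"
  )
}

#' Correlation-scaled forecast of a target year's weekly counts
#'
#' Predicted count for week `w` of the target year is
#' `r_mean * source count at week w`, paired by ISO week number. If the
#' target year has one week more than the source year (ISO week 53, as in
#' 2020), the final source week's value is carried over; if it has one
#' fewer, the extra source week is dropped.
#'
#' @param source `weekly_counts` covering exactly one ISO year (the
#'   pandemic-dataset inclusion year).
#' @param estimate A `correlation_estimate`; `r_mean` must be
#'   non-negative — a negative forecast of counts is meaningless under this
#'   model.
#' @param target_year Integer ISO year to forecast.
#' @return An object of class `forecast_series`: tibble with `iso_year`,
#'   `iso_week`, `predicted`, and attributes `diagnosis`, `stratum`,
#'   `estimate`, `source_year`.
#' @export
scale_forecast <- function(source, estimate, target_year) {
  stopifnot(inherits(source, "weekly_counts"), inherits(estimate, "correlation_estimate"))
  if (length(unique(source$iso_year)) != 1) {
    stop("`source` must cover exactly one ISO year.", call. = FALSE)
  }
  if (estimate$r_mean < 0) {
    stop("r_mean is negative; refusing to forecast negative counts. ",
      "The scaling model assumes a non-negative between-year correlation.",
      call. = FALSE
    )
  }
  n_target <- iso_weeks_in_year(target_year)
  src <- as.numeric(source$count[match(seq_len(nrow(source)), source$iso_week)])
  pred <- estimate$r_mean * src[pmin(seq_len(n_target), length(src))]
  structure(
    tibble::tibble(
      iso_year = rep(as.integer(target_year), n_target),
      iso_week = seq_len(n_target),
      predicted = pred
    ),
    diagnosis = attr(source, "diagnosis"), stratum = attr(source, "stratum"),
    estimate = estimate, source_year = unique(source$iso_year),
    class = c("forecast_series", class(tibble::tibble()))
  )
}

#' Fit the two pandemic-year forecasts for one diagnosis and stratum
#'
#' From the pre-pandemic dataset, estimates the mean Pearson correlation
#' between the inclusion year and each follow year (inclusion vs
#' inclusion+1, inclusion vs inclusion+2) by pairs bootstrap. The pandemic
#' dataset's inclusion-year weekly counts are then multiplied by the first
#' correlation to forecast the first pandemic year and by the second to
#' forecast the second — the correlation decays with lag, encoding the
#' assumption that counts are at most at the inclusion-year level.
#'
#' @param pre_ds Pre-pandemic `analysis_dataset` (spans inclusion + 2
#'   follow years).
#' @param pan_ds Pandemic `analysis_dataset`.
#' @param diagnosis Analysis code.
#' @param strat A [stratum()].
#' @param n_boot Bootstrap resamples per correlation (default 10000).
#' @param seed Integer seed; the second correlation uses `seed + 1`.
#' @return List with elements `first` and `second` (`forecast_series` for
#'   the two pandemic follow years) and `estimates` (list of the two
#'   `correlation_estimate`s).
#' @export
fit_forecasts <- function(pre_ds, pan_ds, diagnosis,
                          strat = stratum("overall"),
                          n_boot = 10000L, seed = NULL) {
  pre_incl <- pre_ds$spec$inclusion_year
  pre_series <- weekly_counts(pre_ds, diagnosis, strat)
  y1 <- slice_years(pre_series, pre_incl)
  estimates <- lapply(1:2, function(k) {
    yk <- slice_years(pre_series, pre_incl + k)
    pairs <- align_weeks(y1, yk)
    bootstrap_mean_correlation(
      pairs$x, pairs$y,
      n_boot = n_boot,
      seed = if (is.null(seed)) NULL else seed + (k - 1L),
      year_pair = c(pre_incl, pre_incl + k)
    )
  })
  pan_incl <- pan_ds$spec$inclusion_year
  source <- slice_years(weekly_counts(pan_ds, diagnosis, strat), pan_incl)
  list(
    first = scale_forecast(source, estimates[[1]], pan_ds$spec$follow_years[1]),
    second = scale_forecast(source, estimates[[2]], pan_ds$spec$follow_years[2]),
    estimates = estimates
  )
}

#' Write forecast series to CSV
#'
#' Columns: `diagnosis,stratum,target_year,iso_week,predicted,r_mean,r_sd,seed`.
#'
#' @param forecasts A `forecast_series` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_forecasts <- function(forecasts, path) {
  if (inherits(forecasts, "forecast_series")) forecasts <- list(forecasts)
  rows <- purrr::map(forecasts, function(f) {
    est <- attr(f, "estimate")
    tibble::tibble(
      diagnosis = attr(f, "diagnosis"),
      stratum = format(attr(f, "stratum")),
      target_year = f$iso_year, iso_week = f$iso_week, predicted = f$predicted,
      r_mean = est$r_mean, r_sd = est$r_sd,
      seed = if (is.null(est$seed)) NA_integer_ else est$seed
    )
  })
  readr::write_csv(dplyr::bind_rows(rows), path)
  invisible(path)
}
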