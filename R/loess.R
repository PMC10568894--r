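#' Loess smooth of a weekly series with pointwise standard errors
#'
#' Locally weighted polynomial regression (tricube kernel) of a weekly
#' series on its week index, evaluated at every design point with a
#' pointwise standard error. The default span of 0.17 (17% of points in
#' each local neighbourhood) retains seasonal irregularities while showing
#' the overall trend; degree-2 local polynomials are the default. Exact
#' (non-interpolated) surface and exact variance statistics are used so
#' results are deterministic and reproducible to machine precision.
#'
#' @param y Numeric weekly values (no NAs).
#' @param x Numeric design points; default consecutive week indices.
#' @param span Fraction of points in each local neighbourhood, in (0, 1].
#' @param degree Local polynomial degree (0, 1 or 2).
#' @return A `loess_fit` tibble with columns `x`, `y`, `fitted`, `se` and
#'   attributes `span`, `degree`, `df` (residual degrees of freedom used
#'   for t-based bands), `s` (residual scale).
#' @examples
#' fit <- loess_fit(3 + 2 * (1:52) + rnorm(52), span = 0.5)
#' @export
loess_fit <- function(y, x = seq_along(y), span = 0.17, degree = 2) {
  y <- as.numeric(y)
  x <- as.numeric(x)
  if (anyNA(y) || anyNA(x)) stop("NA/NaN in input.", call. = FALSE)
  if (span <= 0 || span > 1) stop("`span` must be in (0, 1].", call. = FALSE)
  n <- length(y)
  if (n < max(4, ceiling(span * n))) stop("Too few points for loess.", call. = FALSE)

  fit <- stats::loess(
    y ~ x,
    span = span, degree = degree, family = "gaussian",
    control = stats::loess.control(surface = "direct", statistics = "exact")
  )
  pr <- stats::predict(fit, se = TRUE)
  structure(
    tibble::tibble(x = x, y = y, fitted = as.numeric(pr$fit), se = as.numeric(pr$se.fit)),
    span = span, degree = degree, df = pr$df, s = fit$s,
    class = c("loess_fit", class(tibble::tibble()))
  )
}

#' Pointwise confidence band around a loess fit
#'
#' `fitted +/- q * se` at each design point, where `q` is the two-sided
#' quantile at the given level: the standard normal quantile by default
#' (for level 0.999, q ~ 3.2905), or a t quantile on the fit's residual
#' degrees of freedom.
#'
#' @param fit A [loess_fit()] result.
#' @param level Coverage level in (0, 1); default 0.999, reflecting that
#'   the forecast rests on a single pre-pandemic observation period.
#' @param quantile `"normal"` (default) or `"t"`.
#' @return Tibble with columns `ci_lower`, `ci_upper`.
#' @export
pointwise_band <- function(fit, level = 0.999, quantile = c("normal", "t")) {
  stopifnot(inherits(fit, "loess_fit"))
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("`level` must be in (0, 1).", call. = FALSE)
  }
  quantile <- match.arg(quantile)
  p <- 1 - (1 - level) / 2
  q <- if (quantile == "normal") stats::qnorm(p) else stats::qt(p, df = attr(fit, "df"))
  tibble::tibble(ci_lower = fit$fitted - q * fit$se, ci_upper = fit$fitted + q * fit$se)
}

#' Mean deviation between observed and predicted weekly counts
#'
#' The headline effect measure:
#' `100 * sum(|observed_w - predicted_w|) / sum(predicted_w)` over the
#' analysis window, computed on raw weekly counts. The absolute value
#' prevents excess and deficit weeks from cancelling; the statistic is
#' invariant to a common rescaling of both series and zero only when the
#' series coincide.
#'
#' @param observed,predicted Equal-length numeric weekly vectors;
#'   `sum(predicted)` must be positive.
#' @return The mean deviation, in percent (non-negative scalar).
#' @examples
#' mean_deviation(c(110, 90), c(100, 100)) # 10
#' @export
mean_deviation <- function(observed, predicted) {
  observed <- as.numeric(observed)
  predicted <- as.numeric(predicted)
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal length.", call. = FALSE)
  }
  tot <- sum(predicted)
  if (!is.finite(tot) || tot <= 0) {
    stop("Sum of predicted counts must be positive.", call. = FALSE)
  }
  100 * sum(abs(observed - predicted)) / tot
}

#' Maximal runs of consecutive flagged weeks
#'
#' @param flags Character vector of per-week flags (`"above"`, `"below"`,
#'   `"none"`).
#' @param iso_year,iso_week Parallel week identifiers.
#' @return Tibble with one row per maximal run of a single non-`"none"`
#'   flag: `start_iso_year`, `start_iso_week`, `end_iso_year`,
#'   `end_iso_week`, `direction`, `n_weeks`.
#' @export
significant_periods <- function(flags, iso_year, iso_week) {
  stopifnot(length(flags) == length(iso_year), length(flags) == length(iso_week))
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "none"
  tibble::tibble(
    start_iso_year = iso_year[starts[keep]],
    start_iso_week = iso_week[starts[keep]],
    end_iso_year = iso_year[ends[keep]],
    end_iso_week = iso_week[ends[keep]],
    direction = r$values[keep],
    n_weeks = r$lengths[keep]
  )
}

#' Compare observed pandemic counts with the correlation-scaled forecast
#'
#' Smooths the observed and predicted weekly series with loess over the
#' full pandemic span (so the displayed window suffers no edge effect at
#' its start), builds the pointwise confidence band around the predicted
#' smooth, restricts to the analysis window (default 2020-W11, the week
#' the first strict confinement measures began, through the end of the
#' series), flags weeks where the observed smooth exits the band, collects
#' maximal flagged runs, and computes the mean-deviation percentage on the
#' raw counts within the window.
#'
#' @param observed `weekly_counts` covering the pandemic follow years.
#' @param forecast_first,forecast_second `forecast_series` for the two
#'   follow years (from [fit_forecasts()]).
#' @param window_start Integer pair `c(iso_year, iso_week)`; default
#'   `c(2020, 11)`.
#' @param span,level,quantile Passed to [loess_fit()] and
#'   [pointwise_band()].
#' @return An object of class `comparison_result`: list with `table`
#'   (per-window-week tibble: `iso_year`, `iso_week`, `week_index`,
#'   `observed`, `predicted`, `obs_smooth`, `pred_smooth`, `ci_lower`,
#'   `ci_upper`, `flag`), `periods`, `mean_deviation_pct`, `diagnosis`,
#'   `stratum`, `estimates`, and the smoothing settings.
#' @export
compare_to_forecast <- function(observed, forecast_first, forecast_second,
                                window_start = c(2020L, 11L),
                                span = 0.17, level = 0.999,
                                quantile = c("normal", "t")) {
  quantile <- match.arg(quantile)
  stopifnot(inherits(observed, "weekly_counts"))
  pred <- dplyr::bind_rows(
    tibble::as_tibble(forecast_first)[, c("iso_year", "iso_week", "predicted")],
    tibble::as_tibble(forecast_second)[, c("iso_year", "iso_week", "predicted")]
  )
  obs <- tibble::as_tibble(observed)[, c("iso_year", "iso_week", "count")]
  tab <- dplyr::inner_join(pred, obs, by = c("iso_year", "iso_week"))
  if (nrow(tab) != nrow(pred)) {
    stop("Observed series does not cover the forecast span.", call. = FALSE)
  }
  tab <- tab[order(tab$iso_year, tab$iso_week), ]
  tab$week_index <- week_index(tab$iso_year, tab$iso_week, min(tab$iso_year))

  obs_fit <- loess_fit(tab$count, tab$week_index, span = span, degree = 2)
  pred_fit <- loess_fit(tab$predicted, tab$week_index, span = span, degree = 2)
  band <- pointwise_band(pred_fit, level = level, quantile = quantile)

  tab$observed <- as.numeric(tab$count)
  tab$obs_smooth <- obs_fit$fitted
  tab$pred_smooth <- pred_fit$fitted
  tab$ci_lower <- band$ci_lower
  tab$ci_upper <- band$ci_upper
  tab$flag <- dplyr::case_when(
    tab$obs_smooth > tab$ci_upper ~ "above",
    tab$obs_smooth < tab$ci_lower ~ "below",
    .default = "none"
  )

  in_window <- tab$iso_year > window_start[1] |
    (tab$iso_year == window_start[1] & tab$iso_week >= window_start[2])
  if (!any(in_window)) stop("Window not covered by the series.", call. = FALSE)
  win <- tab[in_window, c(
    "iso_year", "iso_week", "week_index", "observed", "predicted",
    "obs_smooth", "pred_smooth", "ci_lower", "ci_upper", "flag"
  )]

  structure(
    list(
      table = win,
      periods = significant_periods(win$flag, win$iso_year, win$iso_week),
      mean_deviation_pct = mean_deviation(win$observed, win$predicted),
      diagnosis = attr(observed, "diagnosis"),
      stratum = attr(observed, "stratum"),
      estimates = list(
        first = attr(forecast_first, "estimate"),
        second = attr(forecast_second, "estimate")
      ),
      span = span, level = level, quantile = quantile,
      window_start = as.integer(window_start)
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> %s / %s: mean deviation %.1f%%, %d significant period(s) over %d weeks\n",
    x$diagnosis, format(x$stratum), x$mean_deviation_pct,
    nrow(x$periods), nrow(x$table)
  ))
  invisible(x)
}
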