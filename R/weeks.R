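#' ISO-8601 week helpers
#'
#' All weekly aggregation uses ISO-8601 week numbering: weeks start on
#' Monday, week 1 is the week containing January 4th, and the ISO year of a
#' date near a year boundary may differ from its calendar year. This makes
#' "week 11 of 2020" (2020-03-09 to 2020-03-15, the week Norway's first
#' strict confinement measures began) well defined.
#'
#' @param date A `Date` vector.
#' @return `iso_year()` and `iso_week()` return integer vectors.
#' @examples
#' iso_week(as.Date("2020-03-12")) # 11
#' iso_year(as.Date("2021-01-01")) # 2020 (ISO week 53 of 2020)
#' @export
iso_year <- function(date) as.integer(format(date, "%G"))

#' @rdname iso_year
#' @export
iso_week <- function(date) as.integer(format(date, "%V"))

#' Number of ISO weeks in an ISO year
#'
#' 52 for most years, 53 when the year ends mid-week (e.g. 2020).
#'
#' @param year Integer ISO year(s).
#' @return Integer vector of 52s and 53s.
#' @examples
#' iso_weeks_in_year(2020) # 53
#' @export
iso_weeks_in_year <- function(year) {
  # Dec 28 always falls in the last ISO week of its year.
  iso_week(as.Date(sprintf("%d-12-28", year)))
}

#' Monday of a given ISO year/week
#'
#' @param year Integer ISO year.
#' @param week Integer ISO week (1..52/53).
#' @return A `Date` vector of Mondays.
#' @export
iso_week_monday <- function(year, week) {
  jan4 <- as.Date(sprintf("%d-01-04", year))
  wday <- (as.POSIXlt(jan4)$wday + 6L) %% 7L # 0 = Monday
  jan4 - wday + 7L * (week - 1L)
}

# Complete (iso_year, iso_week) grid covering ISO years from..to.
iso_week_grid <- function(from, to) {
  years <- seq.int(from, to)
  tibble::tibble(
    iso_year = rep(years, iso_weeks_in_year(years)),
    iso_week = unlist(lapply(iso_weeks_in_year(years), seq_len), use.names = FALSE)
  )
}

# Consecutive week index over a grid (1-based, continuous across years).
week_index <- function(iso_year, iso_week, origin_year, origin_week = 1L) {
  years <- seq.int(origin_year, max(iso_year))
  offsets <- c(0L, cumsum(iso_weeks_in_year(years)))
  offsets[match(iso_year, years)] + iso_week - origin_week + 1L
}
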