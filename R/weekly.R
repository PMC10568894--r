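#' Define a stratum for weekly aggregation
#'
#' Analyses run overall, by gender (`male`/`female`) or by age group
#' (`18-24`, `25-39`, `40-65`; ages fixed at the inclusion year).
#'
#' @param mode One of `"overall"`, `"gender"`, `"age_group"`.
#' @param level Stratum label, required unless `mode = "overall"`.
#' @return An object of class `stratum`.
#' @examples
#' stratum("gender", "female")
#' @export
stratum <- function(mode = c("overall", "gender", "age_group"), level = NULL) {
  mode <- match.arg(mode)
  valid <- switch(mode,
    overall = NULL, gender = c("male", "female"), age_group = age_groups()
  )
  if (mode == "overall") {
    level <- NULL
  } else if (is.null(level) || !level %in% valid) {
    stop("`level` must be one of ", paste(valid, collapse = ", "),
      " for mode '", mode, "'.",
      call. = FALSE
    )
  }
  structure(list(mode = mode, level = level), class = "stratum")
}

#' @export
format.stratum <- function(x, ...) {
  if (x$mode == "overall") "overall" else paste0(x$mode, ":", x$level)
}

#' @export
print.stratum <- function(x, ...) {
  cat("<stratum>", format(x), "\n")
  invisible(x)
}

parse_stratum <- function(s) {
  if (s == "overall") {
    return(stratum("overall"))
  }
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  stratum(parts[1], parts[2])
}

#' All default strata
#'
#' Overall, both genders, and the three age groups — the strata the
#' stratified analyses run over.
#'
#' @return List of [stratum()] objects.
#' @export
default_strata <- function() {
  c(
    list(stratum("overall")),
    lapply(c("male", "female"), function(l) stratum("gender", l)),
    lapply(age_groups(), function(l) stratum("age_group", l))
  )
}

new_weekly_counts <- function(points, diagnosis, stratum) {
  points <- points[order(points$iso_year, points$iso_week), , drop = FALSE]
  structure(
    tibble::as_tibble(points),
    diagnosis = diagnosis, stratum = stratum,
    class = c("weekly_counts", class(tibble::tibble()))
  )
}

#' Weekly consultation counts for one diagnosis and stratum
#'
#' Aggregates the retained consultations of an analysis dataset to total
#' counts per ISO week, for one analysis code and one stratum. Every
#' consultation counts (a patient with three consultations in a week
#' contributes three), and a consultation carrying two analysis codes
#' contributes one count to each code's series. The grid is complete over
#' the dataset span (inclusion year through last follow year): weeks with
#' no consultations appear with count 0.
#'
#' @param ds An [build_dataset()] result.
#' @param diagnosis One analysis code (e.g. `"P74"`).
#' @param stratum A [stratum()]; default overall.
#' @return A `weekly_counts` tibble with columns `iso_year`, `iso_week`,
#'   `count` and attributes `diagnosis`, `stratum`.
#' @export
weekly_counts <- function(ds, diagnosis, stratum = mhconsult::stratum("overall")) {
  stopifnot(inherits(ds, "analysis_dataset"), inherits(stratum, "stratum"))
  diagnosis <- toupper(diagnosis)
  if (!diagnosis %in% ds$spec$codes$analysis_codes) {
    stop("`diagnosis` must be one of the analysis codes: ",
      paste(ds$spec$codes$analysis_codes, collapse = ", "),
      call. = FALSE
    )
  }
  members <- stratum_members(ds, stratum)
  rows <- ds$code_flags[, diagnosis] & ds$consultations$patient_id %in% members
  dates <- ds$consultations$date[rows]

  grid <- iso_week_grid(ds$spec$inclusion_year, max(ds$spec$follow_years))
  if (length(dates) > 0) {
    counted <- dplyr::count(
      tibble::tibble(iso_year = iso_year(dates), iso_week = iso_week(dates)),
      .data$iso_year, .data$iso_week,
      name = "count"
    )
    grid <- dplyr::left_join(grid, counted, by = c("iso_year", "iso_week"))
    grid$count[is.na(grid$count)] <- 0L
  } else {
    grid$count <- 0L
  }
  grid$count <- as.integer(grid$count)
  new_weekly_counts(grid, diagnosis = diagnosis, stratum = stratum)
}

stratum_members <- function(ds, stratum) {
  pop <- ds$population
  switch(stratum$mode,
    overall = pop$patient_id,
    gender = pop$patient_id[pop$gender == stratum$level],
    age_group = pop$patient_id[!is.na(pop$age_group) & pop$age_group == stratum$level]
  )
}

#' Restrict a weekly series to given ISO years
#'
#' @param series A `weekly_counts` tibble.
#' @param years Integer ISO years to keep.
#' @return The sub-series (grid completeness within those years preserved).
#' @export
slice_years <- function(series, years) {
  stopifnot(inherits(series, "weekly_counts"))
  out <- series[series$iso_year %in% years, , drop = FALSE]
  if (nrow(out) == 0) warning("slice_years(): no overlap with ", paste(years, collapse = ", "), call. = FALSE)
  new_weekly_counts(out, attr(series, "diagnosis"), attr(series, "stratum"))
}

#' Pair two single-year weekly series week-by-week
#'
#' Pairs counts by ISO week number over weeks `1..min(length_a, length_b)`;
#' a 53rd week present in only one year is left unpaired.
#'
#' @param series_a,series_b `weekly_counts` covering exactly one ISO year
#'   each.
#' @return A list with numeric vectors `x` (from `series_a`) and `y` (from
#'   `series_b`) of equal length.
#' @export
align_weeks <- function(series_a, series_b) {
  for (s in list(series_a, series_b)) {
    if (nrow(s) == 0) stop("align_weeks(): empty series.", call. = FALSE)
    if (length(unique(s$iso_year)) != 1) {
      stop("align_weeks(): each series must cover exactly one ISO year.", call. = FALSE)
    }
  }
  n <- min(nrow(series_a), nrow(series_b))
  list(
    x = as.numeric(series_a$count[match(seq_len(n), series_a$iso_week)]),
    y = as.numeric(series_b$count[match(seq_len(n), series_b$iso_week)])
  )
}
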