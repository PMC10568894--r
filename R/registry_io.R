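#' Read a consultation-level registry extract
#'
#' Reads a delimited-text consultation extract: one row per reimbursed GP
#' contact with columns `patient_id`, `date` (ISO-8601), `diagnosis_codes`
#' (one or more ICPC-2 codes separated by `code_sep`), and `contact_type`
#' (one of the eight categories in [contact_types()]). Codes are
#' case-normalised to upper case and de-duplicated (set semantics within a
#' consultation). Any malformed row is a located error, never a silent drop.
#'
#' @param path Path to a UTF-8, comma-delimited file with a header row.
#' @param code_sep Separator between codes within the `diagnosis_codes`
#'   cell. Default `";"`.
#' @return A tibble of validated consultation records with columns
#'   `patient_id` (character), `date` (`Date`), `diagnosis_codes`
#'   (list of character vectors), `contact_type` (character). Row order is
#'   preserved.
#' @examples
#' f <- system.file("extdata", "toy_consultations.csv", package = "mhconsult")
#' read_consultations(f)
#' @export
read_consultations <- function(path, code_sep = ";") {
  raw <- read_registry_file(path, c("patient_id", "date", "diagnosis_codes", "contact_type"))
  if (nrow(raw) == 0) {
    warning("Empty consultations file: ", path, call. = FALSE)
    return(tibble::tibble(
      patient_id = character(), date = as.Date(character()),
      diagnosis_codes = list(), contact_type = character()
    ))
  }
  line <- seq_len(nrow(raw)) + 1L # header is line 1

  date <- as.Date(raw$date, format = "%Y-%m-%d")
  bad_date <- is.na(date)
  if (any(bad_date)) {
    stop_rows(path, line[bad_date], "unparseable date", raw$date[bad_date])
  }

  codes <- strsplit(toupper(trimws(raw$diagnosis_codes)), code_sep, fixed = TRUE)
  codes <- lapply(codes, function(x) unique(trimws(x)))
  bad_code <- vapply(codes, function(x) length(x) == 0 || !all(is_icpc2(x)), logical(1))
  if (any(bad_code)) {
    stop_rows(
      path, line[bad_code], "invalid ICPC-2 diagnosis code",
      raw$diagnosis_codes[bad_code]
    )
  }

  ct <- trimws(raw$contact_type)
  bad_ct <- !ct %in% contact_types()
  if (any(bad_ct)) {
    stop_rows(path, line[bad_ct], "unknown contact type", ct[bad_ct])
  }

  bad_id <- is.na(raw$patient_id) | raw$patient_id == ""
  if (any(bad_id)) stop_rows(path, line[bad_id], "empty patient_id", raw$patient_id[bad_id])

  tibble::tibble(
    patient_id = raw$patient_id, date = date,
    diagnosis_codes = codes, contact_type = ct
  )
}

#' Read a population table
#'
#' Reads `patient_id`, `gender` (`male`/`female`), `birth_year`. Duplicated
#' patient ids, unknown genders and implausible birth years are errors.
#'
#' @param path Path to a comma-delimited population file with header.
#' @return A tibble keyed by `patient_id` (one row per patient).
#' @examples
#' f <- system.file("extdata", "toy_population.csv", package = "mhconsult")
#' read_population(f)
#' @export
read_population <- function(path) {
  raw <- read_registry_file(path, c("patient_id", "gender", "birth_year"))
  if (nrow(raw) == 0) {
    warning("Empty population file: ", path, call. = FALSE)
    return(tibble::tibble(
      patient_id = character(), gender = character(), birth_year = integer()
    ))
  }
  line <- seq_len(nrow(raw)) + 1L

  dup <- duplicated(raw$patient_id)
  if (any(dup)) {
    stop("Duplicated patient_id in ", path, ": ",
      paste(unique(raw$patient_id[dup]), collapse = ", "),
      call. = FALSE
    )
  }
  gender <- trimws(tolower(raw$gender))
  bad_g <- !gender %in% c("male", "female")
  if (any(bad_g)) stop_rows(path, line[bad_g], "gender must be male/female", raw$gender[bad_g])

  by <- suppressWarnings(as.integer(raw$birth_year))
  this_year <- as.integer(format(Sys.Date(), "%Y"))
  bad_y <- is.na(by) | by < 1900L | by > this_year
  if (any(bad_y)) stop_rows(path, line[bad_y], "birth_year outside [1900, current year]", raw$birth_year[bad_y])

  tibble::tibble(patient_id = raw$patient_id, gender = gender, birth_year = by)
}

#' Write and read weekly count series
#'
#' `write_weekly_counts()` writes one or more [weekly_counts()] series to a
#' comma-delimited file with columns
#' `diagnosis,stratum,iso_year,iso_week,count`; `read_weekly_counts()`
#' reads such a file back. Integer counts round-trip bit-exactly.
#'
#' @param series A weekly-count series (tibble from [weekly_counts()]), or a
#'   list of them.
#' @param path Output (input) file path.
#' @return `write_weekly_counts()` returns `path` invisibly;
#'   `read_weekly_counts()` returns a list of weekly-count series (one per
#'   diagnosis-stratum combination present in the file).
#' @export
write_weekly_counts <- function(series, path) {
  if (inherits(series, "weekly_counts")) series <- list(series)
  rows <- purrr::map(series, function(s) {
    tibble::tibble(
      diagnosis = attr(s, "diagnosis"),
      stratum = format(attr(s, "stratum")),
      iso_year = s$iso_year, iso_week = s$iso_week, count = s$count
    )
  })
  readr::write_csv(dplyr::bind_rows(rows), path)
  invisible(path)
}

#' @rdname write_weekly_counts
#' @export
read_weekly_counts <- function(path) {
  raw <- read_registry_file(path, c("diagnosis", "stratum", "iso_year", "iso_week", "count"))
  raw$iso_year <- as.integer(raw$iso_year)
  raw$iso_week <- as.integer(raw$iso_week)
  raw$count <- as.integer(raw$count)
  groups <- split(raw, list(raw$diagnosis, raw$stratum), drop = TRUE)
  out <- lapply(groups, function(g) {
    new_weekly_counts(
      g[, c("iso_year", "iso_week", "count")],
      diagnosis = g$diagnosis[1], stratum = parse_stratum(g$stratum[1])
    )
  })
  unname(out)
}

# -- internals ---------------------------------------------------------------

read_registry_file <- function(path, required_cols) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  missing <- setdiff(required_cols, names(raw))
  if (length(missing) > 0) {
    stop("Missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  raw
}

stop_rows <- function(path, lines, what, values, max_show = 5) {
  shown <- utils::head(paste0("line ", lines, " ('", values, "')"), max_show)
  more <- if (length(lines) > max_show) sprintf(" and %d more", length(lines) - max_show) else ""
  stop(what, " in ", path, ": ", paste(shown, collapse = ", "), more, call. = FALSE)
}

# TRUE for rows whose code set intersects `set`.
has_any_code <- function(codes, set) {
  vapply(codes, function(x) any(x %in% set), logical(1))
}
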