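#' Specify a cohort: inclusion year, follow years, age window, code sets
#'
#' A cohort consists of patients aged `min_age`-`max_age` (at the inclusion
#' year) with at least one consultation in the inclusion year carrying an
#' inclusion code. The pre-pandemic cohort uses inclusion year 2017 with
#' follow years 2018-2019; the pandemic cohort uses 2019 with 2020-2021.
#' Age is computed as `inclusion_year - birth_year` and fixed at inclusion,
#' so patients do not migrate between age groups mid-series and patients
#' ageing past `max_age` during follow-up are retained.
#'
#' @param inclusion_year Integer ISO year in which membership is earned.
#' @param follow_years Integer vector of follow-up ISO years (default the
#'   two years after `inclusion_year`).
#' @param min_age,max_age Age window (inclusive) at the inclusion year.
#' @param codes A [code_set()].
#' @return An object of class `cohort_spec`.
#' @examples
#' cohort_spec(2019) # pandemic dataset specification
#' @export
cohort_spec <- function(inclusion_year,
                        follow_years = inclusion_year + 1:2,
                        min_age = 18L, max_age = 65L,
                        codes = code_set()) {
  stopifnot(is.numeric(inclusion_year), length(inclusion_year) == 1)
  follow_years <- sort(as.integer(follow_years))
  if (any(follow_years <= inclusion_year - 1L)) {
    stop("`follow_years` must all lie after inclusion_year - 1.", call. = FALSE)
  }
  if (min_age >= max_age) stop("`min_age` must be < `max_age`.", call. = FALSE)
  structure(
    list(
      inclusion_year = as.integer(inclusion_year), follow_years = follow_years,
      min_age = as.integer(min_age), max_age = as.integer(max_age), codes = codes
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> inclusion %d, follow %s, ages %d-%d\n",
    x$inclusion_year, paste(x$follow_years, collapse = "-"), x$min_age, x$max_age
  ))
  invisible(x)
}

#' Identify cohort members
#'
#' Returns the patients who (a) have at least one consultation dated (by ISO
#' year) in the inclusion year carrying at least one inclusion code —
#' symptom codes P03/P01 count here — and (b) fall inside the age window at
#' the inclusion year.
#'
#' @param consultations Tibble from [read_consultations()].
#' @param population Tibble from [read_population()]; must cover every
#'   patient with a qualifying consultation.
#' @param spec A [cohort_spec()].
#' @return Character vector of member `patient_id`s (sorted).
#' @export
identify_cohort <- function(consultations, population, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  qualifying <- consultations$patient_id[
    iso_year(consultations$date) == spec$inclusion_year &
      has_any_code(consultations$diagnosis_codes, spec$codes$inclusion_codes)
  ]
  ids <- unique(qualifying)
  unknown <- setdiff(ids, population$patient_id)
  if (length(unknown) > 0) {
    stop("Patient(s) in consultations but absent from population: ",
      paste(utils::head(unknown, 10), collapse = ", "),
      if (length(unknown) > 10) sprintf(" and %d more", length(unknown) - 10) else "",
      call. = FALSE
    )
  }
  pop <- population[match(ids, population$patient_id), ]
  age <- spec$inclusion_year - pop$birth_year
  sort(ids[age >= spec$min_age & age <= spec$max_age])
}

#' Build an analysis dataset
#'
#' Constructs the analysis dataset for a cohort: identifies members with
#' [identify_cohort()], then retains their consultations dated (ISO year)
#' from the inclusion year through the last follow year that carry at least
#' one analysis code. A consultation carrying only symptom codes (P03/P01)
#' may establish membership but never appears in the dataset.
#'
#' @inheritParams identify_cohort
#' @param label `"pre_pandemic"` or `"pandemic"` (free-form allowed).
#' @return An object of class `analysis_dataset`: a list with elements
#'   `label`, `spec`, `cohort_ids`, `consultations` (retained rows),
#'   `population` (cohort rows with `age` and `age_group` at inclusion),
#'   `code_flags` (logical matrix, rows = retained consultations, columns =
#'   analysis codes), `n_unique_patients`, `n_consultations`.
#' @export
build_dataset <- function(consultations, population, spec, label = "dataset") {
  cohort <- identify_cohort(consultations, population, spec)
  if (length(cohort) == 0) {
    warning("Empty cohort for inclusion year ", spec$inclusion_year, call. = FALSE)
  }
  years <- seq.int(spec$inclusion_year, max(spec$follow_years))
  keep <- consultations$patient_id %in% cohort &
    iso_year(consultations$date) %in% years &
    has_any_code(consultations$diagnosis_codes, spec$codes$analysis_codes)
  retained <- consultations[keep, , drop = FALSE]

  flags <- matrix(FALSE,
    nrow = nrow(retained), ncol = length(spec$codes$analysis_codes),
    dimnames = list(NULL, spec$codes$analysis_codes)
  )
  if (nrow(retained) > 0) {
    for (code in spec$codes$analysis_codes) {
      flags[, code] <- has_any_code(retained$diagnosis_codes, code)
    }
  }

  pop <- population[population$patient_id %in% cohort, , drop = FALSE]
  pop$age <- spec$inclusion_year - pop$birth_year
  pop$age_group <- age_group_of(pop$age)

  structure(
    list(
      label = label, spec = spec, cohort_ids = cohort,
      consultations = retained, population = pop, code_flags = flags,
      n_unique_patients = length(unique(retained$patient_id)),
      n_consultations = nrow(retained)
    ),
    class = "analysis_dataset"
  )
}

#' @export
print.analysis_dataset <- function(x, ...) {
  cat(sprintf(
    "<analysis_dataset '%s'> %d cohort members, %d retained consultations (%d patients), years %d-%d\n",
    x$label, length(x$cohort_ids), x$n_consultations, x$n_unique_patients,
    x$spec$inclusion_year, max(x$spec$follow_years)
  ))
  invisible(x)
}

#' Summarise an analysis dataset
#'
#' Unique-patient counts, percentage of women, and consultation counts per
#' diagnosis code, per gender and per age group.
#'
#' @param ds An [build_dataset()] result.
#' @return A list with elements `patients` (one-row tibble: cohort size,
#'   unique patients with retained consultations, total consultations,
#'   `pct_women`), `by_code`, `by_gender`, `by_age_group` (tibbles of
#'   consultation counts).
#' @export
dataset_summary <- function(ds) {
  stopifnot(inherits(ds, "analysis_dataset"))
  pop <- ds$population
  active <- unique(ds$consultations$patient_id)
  pct_women <- if (length(ds$cohort_ids) > 0) {
    100 * mean(pop$gender[pop$patient_id %in% ds$cohort_ids] == "female")
  } else {
    0
  }
  by_code <- tibble::tibble(
    diagnosis = colnames(ds$code_flags),
    n_consultations = unname(colSums(ds$code_flags))
  )
  patient_attr <- pop[match(ds$consultations$patient_id, pop$patient_id), ]
  by_gender <- dplyr::count(
    tibble::tibble(gender = patient_attr$gender), .data$gender,
    name = "n_consultations"
  )
  by_age <- dplyr::count(
    tibble::tibble(age_group = patient_attr$age_group), .data$age_group,
    name = "n_consultations"
  )
  list(
    patients = tibble::tibble(
      n_cohort = length(ds$cohort_ids),
      n_unique_patients = length(active),
      n_consultations = ds$n_consultations,
      pct_women = pct_women
    ),
    by_code = by_code, by_gender = by_gender, by_age_group = by_age
  )
}

#' Write a dataset manifest for reproducibility audits
#'
#' JSON manifest with the cohort specification, counts, and an MD5 checksum
#' of the retained consultations (canonical CSV serialisation), so a re-run
#' can be verified byte-for-byte.
#'
#' @param ds An `analysis_dataset`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_dataset_manifest <- function(ds, path) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  flat <- ds$consultations
  flat$diagnosis_codes <- vapply(
    flat$diagnosis_codes, function(x) paste(sort(x), collapse = ";"), character(1)
  )
  readr::write_csv(flat[order(flat$date, flat$patient_id), ], tmp)
  manifest <- list(
    label = ds$label,
    spec = list(
      inclusion_year = ds$spec$inclusion_year,
      follow_years = ds$spec$follow_years,
      min_age = ds$spec$min_age, max_age = ds$spec$max_age,
      inclusion_codes = ds$spec$codes$inclusion_codes,
      analysis_codes = ds$spec$codes$analysis_codes
    ),
    n_cohort = length(ds$cohort_ids),
    n_unique_patients = ds$n_unique_patients,
    n_consultations = ds$n_consultations,
    consultations_md5 = unname(tools::md5sum(tmp))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
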