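#' ICPC-2 code sets for cohort inclusion and analysis
#'
#' The cohort is defined by seven ICPC-2 codes: five disorder codes
#' (depressive disorder P76, anxiety disorder P74, phobia/OCD P79, PTSD P82,
#' eating disorders P86) plus the two symptom codes feeling depressed (P03)
#' and feeling anxious (P01). Symptom codes count towards cohort inclusion —
#' symptoms may later develop into the corresponding disorder — but are
#' excluded from the analysis series, which track disorder codes only.
#'
#' @param inclusion_codes Character vector of ICPC-2 codes that qualify a
#'   patient for cohort membership in the inclusion year.
#' @param analysis_codes Character vector of ICPC-2 codes whose consultations
#'   are retained and counted in the analysis. Must be a subset of
#'   `inclusion_codes`.
#' @param display_names Named character vector mapping codes to labels.
#' @return An object of class `code_set`.
#' @examples
#' cs <- code_set()
#' cs$analysis_codes
#' @export
code_set <- function(inclusion_codes = c("P03", "P76", "P01", "P74", "P79", "P82", "P86"),
                     analysis_codes = c("P76", "P74", "P79", "P82", "P86"),
                     display_names = c(
                       P03 = "Feeling depressed", P76 = "Depressive disorder",
                       P01 = "Feeling anxious", P74 = "Anxiety disorder",
                       P79 = "Phobia/OCD", P82 = "PTSD",
                       P86 = "Eating disorders"
                     )) {
  inclusion_codes <- toupper(inclusion_codes)
  analysis_codes <- toupper(analysis_codes)
  bad <- c(inclusion_codes, analysis_codes)[!is_icpc2(c(inclusion_codes, analysis_codes))]
  if (length(bad) > 0) {
    stop("Invalid ICPC-2 code(s): ", paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  if (!all(analysis_codes %in% inclusion_codes)) {
    stop("`analysis_codes` must be a subset of `inclusion_codes`.", call. = FALSE)
  }
  structure(
    list(
      inclusion_codes = inclusion_codes,
      analysis_codes = analysis_codes,
      display_names = display_names
    ),
    class = "code_set"
  )
}

#' @export
print.code_set <- function(x, ...) {
  cat("<code_set>\n")
  cat("  inclusion:", paste(x$inclusion_codes, collapse = ", "), "\n")
  cat("  analysis: ", paste(x$analysis_codes, collapse = ", "), "\n")
  invisible(x)
}

# ICPC-2 codes are one letter + two digits (e.g. P74).
is_icpc2 <- function(x) grepl("^[A-Z][0-9]{2}$", x)

#' Reimbursement contact-type categories
#'
#' The eight reimbursed GP contact categories: in-person and electronic
#' consultations with a GP or the out-of-hours (ooh) service, each during
#' daytime or evening/night. Any other category in an input file is an error.
#'
#' @return Character vector of the eight valid contact-type codes.
#' @export
contact_types <- function() {
  c(
    "gp_day", "gp_evening", "ooh_day", "ooh_evening",
    "gp_e_day", "gp_e_evening", "ooh_e_day", "ooh_e_evening"
  )
}

#' Age-group labels used for stratification
#'
#' @return Character vector `c("18-24", "25-39", "40-65")`.
#' @export
age_groups <- function() c("18-24", "25-39", "40-65")

# Assign an age (in whole years) to an age-group label; NA outside 18-65.
age_group_of <- function(age) {
  cut(age,
    breaks = c(17, 24, 39, 65), labels = age_groups(),
    right = TRUE
  ) |> as.character()
}
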