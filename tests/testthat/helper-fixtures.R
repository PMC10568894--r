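# Shared fixture builders. The toy registry under inst/extdata/ is small
# enough to hand-count; the expectations asserted against it are tallied in
# the comments of the tests that use it.

toy_path <- function(name) {
  p <- system.file("extdata", name, package = "mhconsult")
  if (p == "") p <- file.path("../../inst/extdata", name)
  p
}

toy_consultations <- function() read_consultations(toy_path("toy_consultations.csv"))
toy_population <- function() read_population(toy_path("toy_population.csv"))

toy_pandemic_dataset <- function() {
  build_dataset(toy_consultations(), toy_population(),
    cohort_spec(2019),
    label = "pandemic"
  )
}

# In-memory consultation tibble in the validated-record shape.
make_consultations <- function(patient_id, date, codes, contact_type = "gp_day") {
  tibble::tibble(
    patient_id = patient_id,
    date = as.Date(date),
    diagnosis_codes = lapply(codes, function(x) toupper(strsplit(x, ";")[[1]])),
    contact_type = rep_len(contact_type, length(patient_id))
  )
}

make_population <- function(patient_id, gender = "female", birth_year = 1985L) {
  tibble::tibble(
    patient_id = patient_id,
    gender = rep_len(gender, length(patient_id)),
    birth_year = rep_len(as.integer(birth_year), length(patient_id))
  )
}

# A small synthetic registry for property tests (fast to generate).
small_registry <- function(seed = 11, n_patients = 2000, ...) {
  generate_registry(synthetic_config(n_patients = n_patients, seed = seed, ...))
}

# Flatten a consultation tibble to a comparable canonical form.
flatten_consultations <- function(x) {
  out <- x
  out$diagnosis_codes <- vapply(
    x$diagnosis_codes, function(cc) paste(sort(cc), collapse = ";"), character(1)
  )
  out[order(out$date, out$patient_id, out$diagnosis_codes, out$contact_type), ]
}
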