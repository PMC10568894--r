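# Hand-derivation for the toy fixture under the pandemic spec
# (inclusion 2019, follow 2020-2021, ages 18-65 at 2019):
#   p1 P76 2019-W02            -> member
#   p2 P03 2019-W23            -> member (symptom code qualifies)
#   p3 P74 2019-W07            -> member
#   p4 only 2020 consultation  -> excluded (no inclusion-year contact)
#   p5 only 2018 consultation  -> excluded (wrong year)
#   p6 P86 2019-W27            -> member
#   p7 P79;P01 2019-W10        -> member (age 20)
#   p8 P76 2019-W36, born 2003 -> excluded (age 16)
# Members: p1, p2, p3, p6, p7 (5; 3 women).
# Retained consultations (analysis codes, 2019-2021, members only): rows
# 1,2,3 (p1), 5 (p2 P82), 6,7 (p3), 10 (p6), 11 (p7) = 8. p2's P03-only
# row and p7's P01 companion code never enter the counts.

test_that("toy cohort membership follows the inclusion rules", {
  members <- identify_cohort(toy_consultations(), toy_population(), cohort_spec(2019))
  expect_equal(members, c("p1", "p2", "p3", "p6", "p7"))
})

test_that("a patient absent from the population is an error naming the id", {
  cons <- toy_consultations()
  pop <- toy_population()
  expect_error(
    identify_cohort(cons, pop[pop$patient_id != "p3", ], cohort_spec(2019)),
    "absent from population.*p3"
  )
})

test_that("the pandemic dataset retains exactly the hand-counted consultations", {
  ds <- toy_pandemic_dataset()
  expect_equal(ds$n_consultations, 8)
  expect_equal(ds$n_unique_patients, 5)
  # symptom-only consultation established p2's membership but is dropped
  expect_false(any(ds$consultations$patient_id == "p2" &
    iso_year(ds$consultations$date) == 2019))
  expect_true(any(ds$consultations$patient_id == "p2")) # the 2020 P82 row stays
  # non-member p4's 2020 P76 consultation is not retained
  expect_false("p4" %in% ds$consultations$patient_id)
  # every retained consultation carries >= 1 analysis code
  expect_true(all(rowSums(ds$code_flags) >= 1))
})

test_that("dataset summary matches hand counts on the fixture", {
  sm <- dataset_summary(toy_pandemic_dataset())
  expect_equal(sm$patients$n_cohort, 5)
  expect_equal(sm$patients$pct_women, 60) # p1, p3, p6 of 5
  expect_equal(
    sm$by_code$n_consultations[match(c("P76", "P74", "P79", "P82", "P86"), sm$by_code$diagnosis)],
    c(3, 3, 1, 1, 1)
  )
  expect_equal(sum(sm$by_gender$n_consultations), 8)
})

test_that("an inclusion year with no consultations yields an empty dataset with warning", {
  expect_warning(
    ds <- build_dataset(toy_consultations(), toy_population(), cohort_spec(2017)),
    "Empty cohort"
  )
  expect_equal(ds$n_consultations, 0)
  sm <- dataset_summary(ds)
  expect_equal(sm$patients$n_unique_patients, 0)
  expect_true(all(sm$by_code$n_consultations == 0))
})

test_that("datasets with overlapping years share byte-identical consultations", {
  reg <- small_registry(seed = 19)
  pre <- build_dataset(reg$consultations, reg$population, cohort_spec(2017), "pre")
  pan <- build_dataset(reg$consultations, reg$population, cohort_spec(2019), "pan")
  shared <- intersect(pre$cohort_ids, pan$cohort_ids)
  expect_gt(length(shared), 0)
  pick <- function(ds) {
    flatten_consultations(ds$consultations[
      ds$consultations$patient_id %in% shared &
        iso_year(ds$consultations$date) == 2019,
    ])
  }
  expect_identical(pick(pre), pick(pan))
})

test_that("rebuilding from an already-filtered dataset is idempotent when membership is analysis-coded", {
  # symptom codes off, so every member's qualifying consultation survives
  cfg_params <- default_diagnosis_params()
  cfg_params$symptom_prob <- 0
  cfg_params$multi_code_prob <- 0
  reg <- generate_registry(synthetic_config(
    n_patients = 800, seed = 3,
    diagnosis_params = cfg_params
  ))
  ds1 <- build_dataset(reg$consultations, reg$population, cohort_spec(2019), "pan")
  ds2 <- build_dataset(ds1$consultations, reg$population, cohort_spec(2019), "pan")
  expect_equal(ds2$cohort_ids, intersect(ds1$cohort_ids, unique(ds1$consultations$patient_id)))
  expect_equal(
    flatten_consultations(ds2$consultations),
    flatten_consultations(ds1$consultations)
  )
})

test_that("growing the code sets never shrinks cohort or retained counts", {
  cons <- toy_consultations()
  pop <- toy_population()
  narrow_codes <- code_set(
    inclusion_codes = c("P76", "P74"),
    analysis_codes = c("P76", "P74")
  )
  wide <- code_set()
  cohort_narrow <- identify_cohort(cons, pop, cohort_spec(2019, codes = narrow_codes))
  cohort_wide <- identify_cohort(cons, pop, cohort_spec(2019, codes = wide))
  expect_true(all(cohort_narrow %in% cohort_wide))

  ds_narrow <- build_dataset(cons, pop, cohort_spec(2019, codes = code_set(
    analysis_codes = c("P76", "P74")
  )))
  ds_wide <- build_dataset(cons, pop, cohort_spec(2019, codes = wide))
  expect_lte(ds_narrow$n_consultations, ds_wide$n_consultations)
})

test_that("ages and age groups are fixed at the inclusion year", {
  pop <- make_population(c("a", "b"), birth_year = c(2000L, 1955L))
  cons <- make_consultations(
    c("a", "b", "b"),
    c("2019-02-04", "2019-02-04", "2021-02-01"),
    c("P76", "P76", "P76")
  )
  ds <- build_dataset(cons, pop, cohort_spec(2019))
  # b is 64 at inclusion, 66 in 2021: retained anyway (cohort fixed at inclusion)
  expect_equal(sort(ds$cohort_ids), c("a", "b"))
  expect_equal(ds$n_consultations, 3)
  expect_equal(
    ds$population$age_group[match(c("a", "b"), ds$population$patient_id)],
    c("18-24", "40-65")
  )
})
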