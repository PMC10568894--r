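#!/usr/bin/env Rscript
# Step 2 — build the two analysis datasets.
#
# Pre-pandemic dataset: patients aged 18-65 with at least one consultation
# in 2017 carrying any of the seven inclusion codes (P03, P76, P01, P74,
# P79, P82, P86), followed through 2018-2019. Pandemic dataset: same rule
# with inclusion year 2019, followed through 2020-2021. In both, only
# consultations carrying a disorder code (P76, P74, P79, P82, P86) are
# retained for analysis; symptom-only contacts may qualify a patient but
# are never counted.

suppressPackageStartupMessages(library(mhconsult))

cons <- read_consultations("results/data/consultations.csv")
pop <- read_population("results/data/population.csv")
message(sprintf("Read %d consultations, %d patients.", nrow(cons), nrow(pop)))

dir.create("results/cohorts", recursive = TRUE, showWarnings = FALSE)

for (setup in list(
  list(year = 2017L, label = "pre_pandemic"),
  list(year = 2019L, label = "pandemic")
)) {
  ds <- build_dataset(cons, pop, cohort_spec(setup$year), label = setup$label)
  sm <- dataset_summary(ds)
  message(sprintf(
    "%s: cohort %d (%.1f%% women), %d retained consultations from %d patients",
    setup$label, sm$patients$n_cohort, sm$patients$pct_women,
    sm$patients$n_consultations, sm$patients$n_unique_patients
  ))
  print(sm$by_code)
  write_dataset_manifest(ds, sprintf("results/cohorts/%s_manifest.json", setup$label))
  readr::write_csv(sm$by_code, sprintf("results/cohorts/%s_by_code.csv", setup$label))
  readr::write_csv(sm$by_gender, sprintf("results/cohorts/%s_by_gender.csv", setup$label))
  readr::write_csv(sm$by_age_group, sprintf("results/cohorts/%s_by_age.csv", setup$label))
}
message("Manifests and summary tables written under results/cohorts/.")
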