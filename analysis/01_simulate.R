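#!/usr/bin/env Rscript
# Step 1 — simulate a synthetic consultation registry.
#
# The real national registry extracts (reimbursement records + population
# register) are not available for external use, so the workflow runs on a
# synthetic registry with the same statistical structure: seasonal weekly
# consultation intensities with summer/Christmas/Easter dips, gamma-frailty
# patient heterogeneity with persistent year-to-year propensities, symptom
# codes (P03/P01) mixed in alongside the five disorder codes, and a known
# injected pandemic shock so later steps can be judged against the truth.
#
# Here: a 40% excess in PTSD (P82) consultations and a 60% excess in eating
# disorder (P86) consultations from 2020-W11 through 2021-W52 — shaped like
# the excesses the surveillance method is meant to pick up.

suppressPackageStartupMessages(library(mhconsult))

outdir <- "results/data"
shocks <- tibble::tibble(
  code = c("P82", "P86"),
  start_year = 2020L, start_week = 11L,
  end_year = 2021L, end_week = 52L,
  multiplier = c(1.4, 1.6)
)

config <- synthetic_config(
  n_patients = 20000,
  effect_schedule = shocks,
  seed = 20200311
)

message("Simulating registry (", config$n_patients, " patients, years ",
  paste(range(config$years), collapse = "-"), ") ...")
reg <- generate_registry(config, dir = outdir)

message(sprintf(
  "Wrote %s: %d consultations, %d patients, ground truth sidecar included.",
  outdir, nrow(reg$consultations), nrow(reg$population)
))
message("Injected shocks: P82 x1.4 and P86 x1.6 over 2020-W11..2021-W52.")
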