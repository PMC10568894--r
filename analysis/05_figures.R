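#!/usr/bin/env Rscript
# Step 5 — time-series figures.
#
# One panel per diagnosis (overall stratum): observed weekly consultations
# (solid red), correlation-scaled forecast (dashed blue) with its 99.9%
# band (grey), and illustrative strict social-distancing periods shaded
# light blue. The injected P82/P86 excesses should be visible as the
# observed line running above the band for most of the window.

suppressPackageStartupMessages(library(mhconsult))

cons <- read_consultations("results/data/consultations.csv")
pop <- read_population("results/data/population.csv")
pre <- build_dataset(cons, pop, cohort_spec(2017), "pre_pandemic")
pan <- build_dataset(cons, pop, cohort_spec(2019), "pandemic")

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
for (code in code_set()$analysis_codes) {
  fc <- fit_forecasts(pre, pan, code, n_boot = 10000, seed = 42)
  obs <- slice_years(weekly_counts(pan, code), 2020:2021)
  cmp <- compare_to_forecast(obs, fc$first, fc$second)
  fig <- plot_comparison(cmp, default_restriction_periods())
  path <- sprintf("results/figures/%s_overall.pdf", code)
  suppressMessages(ggplot2::ggsave(path, fig, width = 8, height = 4.5))
  message(sprintf(
    "%s: mean deviation %.1f%%, %d flagged period(s) -> %s",
    code, cmp$mean_deviation_pct, nrow(cmp$periods), path
  ))
}
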