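---
title: "Forecasting weekly GP mental-health consultation counts: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting weekly GP mental-health consultation counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mhconsult implements a registry-based surveillance analysis of weekly
general-practitioner (GP) consultation counts for common mental health
problems among adults with a recent, pre-existing mental health problem.
This vignette is the package's own account of the method: the cohort
construction, the correlation-scaled forecast, the loess band comparison,
the mean-deviation statistic, the synthetic registry used for validation,
and the design choices made where the method's description leaves room.

## Cohorts and data model

The raw material is a consultation-level extract — one row per reimbursed
GP contact with a patient id, a date, one or more ICPC-2 diagnosis codes
and one of eight contact-type categories (GP or out-of-hours service,
in-person or e-consultation, daytime or evening/night) — plus a population
table with gender and birth year.

Two datasets are built the same way:

* **Pre-pandemic**: patients aged 18–65 with at least one consultation in
  2017 carrying any of seven codes — the five *disorder* codes P76
  (depressive disorder), P74 (anxiety disorder), P79 (phobia/OCD), P82
  (PTSD), P86 (eating disorders) and the two *symptom* codes P03 (feeling
  depressed) and P01 (feeling anxious) — followed through 2018–2019.
* **Pandemic**: the same rule with inclusion year 2019, followed through
  2020–2021.

Symptom codes count towards inclusion (symptoms may later develop into the
corresponding disorder) but are excluded from all counts: analysis series
track the five disorder codes only. A consultation carrying two analysis
codes contributes one count to each code's series; repeat consultations by
one patient within a week all count.

Three choices here are ours rather than given:

* **Year boundaries are ISO years.** Counts live on an ISO-8601 week grid
  (weeks start Monday; "2020-W11", the week of the first Norwegian
  lockdown, is 2020-03-09 through 2020-03-15). Filtering inclusion and
  follow years by ISO year keeps every grid week complete; calendar-year
  filtering would truncate boundary weeks.
* **Age is fixed at the inclusion year** (`inclusion_year - birth_year`),
  for the 18–65 window and for the age groups 18–24 / 25–39 / 40–65.
  Patients ageing past 65 during follow-up stay in the cohort; nobody
  migrates between age groups mid-series.
* **Strict rebuilding is not idempotent when membership rests on a
  symptom-only contact**: such a patient's qualifying consultation is not
  retained, so rebuilding a dataset from its own retained consultations
  would drop them. This is why the pipeline always rebuilds cohorts from
  the raw extract (and why the test for idempotence constructs a registry
  without symptom-only qualifiers).

## The forecast model

With only one pre-pandemic observation period available, the method
estimates how strongly weekly totals in one year predict the next by a
**pairs bootstrap**: the 52 week-pairs `(x_w, y_w)` of two years' totals
are resampled with replacement B = 10,000 times and the Pearson
correlation of each non-degenerate resample is averaged, giving
`r(2017, 2018)` and `r(2017, 2019)` per diagnosis and stratum. Expected
pandemic-year counts are then

```
predicted_2020(w) = r(2017, 2018) * observed_2019(w)
predicted_2021(w) = r(2017, 2019) * observed_2019(w)
```

paired by ISO week number. The lag-2 correlation is typically below the
lag-1 correlation, encoding the assumption that counts are at most at the
inclusion-year level. The mean correlations are treated as fixed constants
downstream.

Decisions and caveats:

* **Resampling unit.** Week-index pairs are resampled (the classic pairs
  bootstrap on the aggregated weekly totals). A patient-level bootstrap —
  resample patients, rebuild both years' weekly vectors — is provided as
  `bootstrap_mean_correlation_patients()` for sensitivity analysis; on
  synthetic data the two agree to well within their own spread.
* **Week 53.** ISO 2020 has 53 weeks but the 2019 source has 52; the
  final source week's value is carried into week 53. Alignment of a
  52-week and a 53-week year pairs weeks 1..52 and leaves week 53
  unpaired.
* **Degenerate resamples** (a constant resampled vector) are excluded
  from the bootstrap average rather than redrawn; the count of valid
  resamples is recorded. At n = 52 this is a formality, but it must be
  defined.
* **A correlation used as a ratio.** Multiplying counts by a correlation
  coefficient treats a scale-free quantity as a level ratio. The model is
  implemented literally as described; it is coherent only when the
  follow-year/inclusion-year level ratio is itself close to the
  correlation — which the synthetic validation world satisfies by
  construction (below), and which real data need not. This is the
  model's central statistical caveat, reproduced on purpose rather than
  repaired (a trend model would be a different method).
* Every estimate records its seed; the same seed reproduces the same
  forecast byte for byte.

## Smoothing, bands and the deviation statistic

Observed and predicted weekly series are each smoothed by loess (local
quadratic, tricube weights, span 0.17 — about 18 of the 105 pandemic
weeks per neighbourhood) over the full 2020–2021 span, then restricted to
the analysis window 2020-W11 onward, so the window's left edge suffers no
boundary effect. The pointwise band is `fitted ± q × se` around the
*predicted* smooth with q the two-sided normal quantile at 99.9%
(q ≈ 3.2905); a t-quantile keyed to the fit's residual degrees of freedom
is available. A week is flagged when the observed smooth exits the band;
maximal runs of equal flags form the reported periods. The exact
(non-interpolating) loess surface and exact variance statistics are used
throughout, so fits are deterministic and the standard errors match a
direct hat-matrix computation to machine precision.

The headline statistic is the **mean deviation percentage**
`100 × Σ|observed_w − predicted_w| / Σ predicted_w` over the window,
computed on **raw** weekly counts (the statistic speaks about counts, not
about smooths; a smoothed-input variant is a one-line change and gives
near-identical values on smooth series). Two properties matter for
interpretation: the absolute value stops excess and deficit cancelling,
and a no-effect scenario still yields a positive deviation of about
`100(1 − r)/r` when the scaling correlation r is below 1 — the statistic
measures distance from the *forecast*, not from the truth.

Whether significance is judged on the smoothed observed line (our
default) or on raw points, and whether the deviation window starts at
2020-W11 (our default) or 2020-W01, are configuration switches; the
defaults follow the reference display window.

## The synthetic registry

Real national-registry extracts are unavailable for external use, so
validation runs on a generator with known ground truth. Patient `i` with
assigned disorder `d` produces consultations in week `w` of year `y` by a
Poisson process with intensity

```
rate_d * u_iy * s_w * (1 + b cos(2*pi*(w - phi_iy)/52)) * m_d(y, w)
```

* `s_w` — shared seasonal profile: cosine with amplitude 0.25 peaking
  near week 4, a summer-holiday dip (weeks 26–32, factor 0.55), a
  Christmas dip (weeks 51–53, factor 0.5) and an Easter-like dip (week
  15, factor 0.75). These deep shared dips are what make one year's
  weekly profile strongly predictive of the next, as in real
  consultation series.
* `u_iy` — Gamma(2, 2) frailty (mean 1), giving roughly three-fold
  variation between light and heavy attenders and negative-binomial
  weekly marginals.
* `phi_iy`, `b = 0.4` — a patient-specific within-year timing preference;
  with heterogeneous frailties the realised weekly profile carries a
  patient-mix imprint that repeats across years.
* Persistence 0.97: each year a patient keeps `(u, phi)` with probability
  0.97, else redraws both. Correlation between years decays with lag,
  which is why the lag-2 scaling correlation sits below the lag-1.
* `m_d(y, w)` — scheduled multiplicative pandemic shocks, the injected
  ground truth.
* Gender split 0.62 female; age groups 18–24/25–39/40–65 with weights
  0.15/0.33/0.52 anchored at 2019; disorder shares 0.34/0.34/0.13/0.11/0.08
  for P76/P74/P79/P82/P86; for the two common disorders a quarter of
  consultations carry the symptom code (P03/P01) instead of the disorder
  code, and 5% carry both — exercising the inclusion-versus-analysis code
  logic. An optional `registration_loss` drops a fraction of
  final-December consultations, mimicking the late-registration artefact
  seen at the end of such extracts (documented, not corrected).

**Why the default intensities are what they are.** Per-patient weekly
rates are 0.12 (P76, P74), 0.09 (P79, P82) and 0.06 (P86) — effective
annual intensities of roughly 5.8 down to 2.9 once the holiday dips are
netted out. This puts the generator at the regular-attender end of what a
real cohort contains, deliberately: requiring one inclusion-year
consultation deflates follow-year totals among members by the factor
`E[u(1 − exp(−mu*u))]/E[u]` (patients who happened not to consult in the
inclusion year contribute nothing to it but would have contributed to
follow years). At mu ≈ 5.8 and Gamma(2,2) frailty this factor is ≈ 0.98,
so follow-year levels sit within a few percent of the inclusion-year
level and the forecast model's premise holds in the synthetic world; at
rare-attender intensities (mu ≈ 1.5) it falls to ~0.8 and no forecast of
the model's form can be unbiased. The generator, in other words, depicts
the world in which the method is correct — that is what makes recovery of
injected effects a meaningful end-to-end test, and it is also an honest
statement of what passing tests do *not* show about real data, where
regression-to-the-mean from the inclusion rule is folded silently into
the scaling correlations.

A **deterministic mode** sidesteps randomness entirely: fixed non-constant
weekly profiles (multiples of 10), pre-pandemic follow years exact copies
of 2017 (forcing every bootstrap correlation to 1.0 exactly) and pandemic
years exact week-wise multiples of 2019. With multiplier m the pipeline
must return a mean deviation of exactly 100(m − 1) — the end-to-end
identity the test suite asserts for m = 1.0, 1.2, 1.5.

The ground-truth sidecar stores the realised expected weekly counts per
diagnosis — both over all patients and conditional on cohort membership
(inclusion-year expectations are unconditional, since zero-count patients
contribute nothing; follow-year expectations weight each patient by their
membership probability `1 − exp(−Lambda_incl)`) — plus the injected
schedule, which suffices to compute the expected value of every
downstream statistic (`expected_deviation_from_truth()`).

## Problem sizes and numerical choices

Validation simulations use 20,000 patients over 2017–2021 (about 450,000
consultations), 10 replicate seeds for effect recovery (a 1.5× shock on
one diagnosis across the window, recovered within ±5 points of the
analytic oracle `100|1.5 − r|/r`) and 20 replicate seeds for null
calibration (band-exit fraction of window weeks ≤ 5%; deviation near the
no-effect oracle `100|1 − r|/r`). These sizes give stable averages while
keeping the whole suite comfortably runnable on a laptop. Bootstrap
estimates use B = 10,000 (B = 100,000 when checked against exhaustive
enumeration of all 27 resamples of three pairs); loess-band coverage is
assessed over 200 Gaussian-noise replicates around a known curve.

Degenerate inputs are defined, not improvised: constant weekly vectors
make the correlation undefined and are an error (the pipeline records
such strata as skipped — the analogue of dropping a near-empty panel such
as eating disorders among men, rather than aborting); a negative mean
correlation would forecast negative counts and is refused; an empty
cohort yields a valid empty dataset with a warning; files are read with
schema and row-level validation that names the offending line.

## Limitations

* The forecast has no trend or seasonality model of its own; everything
  rides on the inclusion-year profile and two scalar correlations.
* Band exceedance is assessed week by week at 99.9% without multiplicity
  control across weeks or strata, as in the original method: flagged
  periods are descriptive, not formal tests.
* The synthetic registry does not attempt realistic demography, practice
  structure or infection dynamics, and its dependence mechanism (frailty
  plus timing affinity) is one of several that could produce the assumed
  between-year correlation; passing tests validate the pipeline's
  arithmetic and the method's internal logic, not its adequacy for any
  particular real registry.
* Correlations are estimated per diagnosis × stratum; whether a single
  per-diagnosis correlation should be shared across strata is a
  modelling choice the configuration exposes implicitly through the
  stratum list.
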