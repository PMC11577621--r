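---
title: "Benchmarking stroke care pathways from discharge registers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking stroke care pathways from discharge registers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(strokebench)
```

This vignette documents the models behind `strokebench`, the parameters
that matter, and the design decisions taken where register-based practice
leaves the choice open. It states no empirical result that the test suite
and `scripts/acceptance.R` do not themselves compute.

## 1. From stays to episodes

A discharge register records admission intervals, not illness episodes. We
reconstruct each patient's *first institutional episode* — the continuous
run of institutional care that begins with the index stroke admission and
continues through transfers into rehabilitation wards, health centres or
nursing homes.

**Transfer gap rule.** Two stays belong to the same chain when the next
admission is at most `gap_days` after the previous discharge (a running
maximum over earlier discharges, so contained or overlapping records never
break a chain; provider changes never break chains). The register
tradition only says transfers are "considered"; we default to
`gap_days = 1` — admission on the same or the next calendar day continues
the episode — which is the conventional register rule, and keep it a
parameter. Records are sorted by admission first and exact duplicates are
dropped with a warning.

**Index selection.** For every patient and calendar year, the first chain
whose first stroke-coded stay (ICD-10 prefix I60/I61/I63/I64; matching is
on the 3-character prefix because register coding practice varies below
it) falls in that year is the candidate episode. Recurrent strokes enter
later cohorts only via the washout below, which also implements the rule
that a new index requires more than 365 days since the end of the previous
stroke admission; earlier strokes beyond the washout become a
previous-stroke comorbidity flag used in risk adjustment.

**Subtype hierarchy.** Episodes mixing stroke subtype codes take the most
severe: subarachnoid haemorrhage over intracerebral haemorrhage over
cerebral infarction over ill-defined stroke. Only infarction episodes are
analysed; the hierarchy exists so that, e.g., an infarction admission that
turns out to be a haemorrhage during the episode leaves the ischaemic
cohort.

**Cohort filters,** applied in a fixed order so the exclusion log is
deterministic (first matching rule wins): non-ischaemic subtype; a
stroke-coded stay overlapping the 365 days before the index (we test
overlap — admission before the index and discharge within the window — so
a long prior admission discharged 300 days before the index is correctly
treated as recent); an optional incomplete-identity flag; pre-index
long-term care. Counts always satisfy `n_input = n_included + sum of
per-rule exclusions`.

Whether psychiatric stays continue the institutional episode is not
settled in register practice; they do here (they are institutional care,
and they are costed by their own specialty per-diems). This is the one
place our episode definition is wider than a strict somatic reading.

## 2. The nine indicators

Lengths use `end - start` in days with a floor of one day, so same-day
discharges are one-day episodes and count models never see zeros. Death
truncates lengths, day counts, and cost accrual: days after death accrue
nothing, and a stay record extending past the recorded death date is cut
at death.

Day-90 placement is **point-in-time occupancy**: a surviving patient is
institutionalized when some institutional stay covers day 90 after the
index, and home when no stay covers day 90 and the first episode has
ended. This makes home and institutionalized mutually exclusive and gives
the dead neither state. The alternative reading — ever discharged home by
day 90, alive — is implemented behind the `home_rule = "ever_discharged"`
switch; we default to point-in-time because it uses the same horizon
convention as the institutionalization companion indicator.

Inpatient days within one year merge overlapping stay intervals before
counting (an interval union, capped at 365). Costs, by contrast, sum *per
stay*: each admission is billed separately at its per-diem rate, so
overlapping admission records are both charged, mirroring per-admission
invoicing. The per-diem rates are: the annual median of admission cost per
day within each acute cost group (a DRG stand-in), with the all-acute
annual median as fallback (`median_cost_per_day()`; even-count medians are
the mean of the two middle values); specialty medians for psychiatry;
standard daily rates for health-centre, nursing-home and other long-term
care. No discounting or inflation adjustment happens inside the pipeline:
the cost table is assumed to be at one reference price level already.

## 3. Difference-in-differences

All DID fits are OLS on individual-level data, including for binary
outcomes (a linear probability model): transforming a nonlinear model's
coefficients into the DID contrast does not identify the effect
consistently, so linearity is the defensible default and the paper-trail
models (logistic, negative binomial, gamma) are used only for adjusted
*descriptions* — baseline marginals and trend figures.

The default time structure is year indicators plus a single
treated-by-post interaction; a plain pre/post dummy is available
(`time_structure = "prepost"`). With no covariates and balanced cells the
estimator reduces exactly to the difference of cell-mean differences (the
suite checks agreement to 1e-10). Standard errors are
heteroskedasticity-consistent (HC1); with a single treated region there is
no meaningful cluster level above the patient, so we do not cluster. The
first year after each reform is excluded as its implementation year.

**Parallel trends.** On pre-period data we fit OLS with the region dummy,
covariates, and region-by-time interactions for four time
parameterizations — annual indicators, linear, logarithmic, and quadratic
trends — and report the joint interaction F-test per family, with the
strongest of the three parametric trends summarized as the "trend"
verdict. At least three distinct pre-years are required. A rejection is
evidence against the common-trend assumption, not proof of it holding.

**Kernel propensity matching.** The sensitivity analysis estimates the
propensity of treated-region membership by logistic regression on the
covariates, weights each control by the average Epanechnikov kernel
`K(u) = 0.75(1 - u^2), |u| < 1` over its distances to all treated scores
(`u = (p_c - p_t) / 0.06` by default), normalizes weights to mean one
within the on-support controls, drops zero-mass controls with a logged
count, and refits the weighted OLS DID. The target distribution question —
match each control to each treated observation or to a treated summary —
is resolved as per-treated-observation kernel mass, averaged. Standard
errors come from resampling patients with replacement and re-estimating
propensity, weights and the weighted fit each time; 5,000 replicates by
default, with percentile p-values when at least 1,000 replicates are
available and a normal approximation below that. When all propensity
scores coincide the weights are uniform and the estimator collapses onto
plain OLS (checked to 1e-8); as the bandwidth grows the weights flatten to
uniform.

## 4. Rolling-cohort trends

The figure methodology refits the indicator models on overlapping 365-day
cohorts advanced by 30 days: window `k` starts at `first_start + 30k` and
a patient belongs to every window containing their index date (a half-open
`[start, start + 365)` interval — the printed first and second window
starts force the overlapping reading; each patient sits in at most 13
windows). Outcomes needing follow-up use each patient's own 365-day
follow-up even when it extends past the window end: windows select
cohorts, they never truncate measurement. Per window we fit the
family-appropriate model — logistic for dichotomous outcomes, negative
binomial for counts (falling back to Poisson when the dispersion estimate
diverges, which is the Poisson limit), gamma with log link for costs
(degenerate constant-outcome windows short-circuit to the constant) — and
report the average marginal estimate per region: predictions with every
observation assigned to that region, averaged, with delta-method standard
errors. Sparse or non-convergent windows are flagged in the series rather
than dropped.

## 5. The synthetic register

The generator emulates what the analysis needs from a national discharge
register; its defaults are the study conditions of the test suite.

* **Regions and baselines.** Three regions (a treated city of about 2% of
  patients, the rest of its region, the rest of the country) with
  per-region baselines on the indicator scale: mean acute and episode
  length among 90-day survivors, unconditional day-90 institutionalization,
  and 90-day / 1-year mortality. The defaults (city episode mean 30.3
  days, institutionalization 16.8%, 90-day mortality 15.9%, against
  country-wide 27.0 days / 11.5% / 14.5%) are the magnitudes a stroke
  register of the 2000s shows, with the city starting worse — the setting
  whose reform one would benchmark. Annual secular drifts (about −0.3
  days/year on lengths, −0.2 to −0.35 points/year on event probabilities)
  reproduce the era's general improvement in stroke care.
* **Why institutionalization is the free placement parameter.** With
  point-in-time placement, home and institutionalized partition the
  day-90 survivors, so only one of the two probabilities is free; we
  parameterize the institutionalization side and let home discharge
  emerge. The configured value is the *unconditional* share (alive and in
  care), converted internally to a conditional probability among
  survivors, which keeps configured intervention effects on the scale the
  DID measures.
* **Exact injection.** Probability targets are hit exactly in expectation
  by a calibrated shift on the logit scale on top of covariate effects
  (comorbidity and age effects enter on log-odds for events and
  multiplicatively, mean-normalized, for lengths — the scales the
  description models use). Length effects are injected into the
  survivor-level draw scaled by 1/P(alive at 90), because patients dying
  within 90 days die in care (their episode length is their survival time)
  and carry no intervention signal; the day-90 home cap is compensated
  analytically (a fixed point of the censored shape-2 gamma mean) so the
  capped draw still has the target mean. Net: a configured effect *is* the
  true DID effect on the measured indicator, which is what makes the
  recovery studies meaningful.
* **Costs.** Per-diem rates are national (cost-group multipliers around a
  500/day acute rate, 200/150 for health-centre/nursing-home days), as
  per-diem costing implies, so regional cost differences arise through
  days of care and case mix, not prices. Consequently cost-side
  intervention effects are not directly injectable — they emerge from
  length effects — and the ground truth carries effects for the five
  controllable parameters (acute and episode length,
  institutionalization, both mortality horizons).
* **What it does not emulate.** Outpatient care and medication (the cost
  indicators deliberately cover inpatient care only), realistic geography,
  seasonal admission patterns, coding errors beyond planted duplicates,
  and stroke-severity case mix (severity is unobserved in registers; the
  generator's comorbidities stand in for observable case mix only).
  Passing recovery tests therefore shows the estimators are consistent
  under the generator's assumptions — notably parallel trends by
  construction — not that real-register confounding is solved.

Death offsets are drawn in 1–89 days (90-day deaths) and 91–364 days
(late deaths), so no deaths occur on the admission day and the two
mortality indicators are independently controllable; episode draws are
shape-2 gammas (coefficient of variation 0.7, the right dispersion order
for length-of-stay data) rounded to whole days with a floor of one.

## 6. Study conditions and numerical choices

The calibration studies fix their scenarios inside the package
(`study_recovery()`, `study_type1()`, `study_trend_power()`):

* recovery: ~5,000 treated-region and ~50,000 control patients across 11
  analysed cohort years, effects −4.0 days on episode length and −5.1
  points on institutionalization injected from 2006, 20 replicates by
  default with per-outcome ±2-SE coverage reported;
* type-I: a null scenario of 100 patients/year over four cohort years with 500
  bootstrap replicates for the kernel-matched estimator (its default of
  5,000 is impractical inside a simulation loop and the normal
  approximation is accurate at this scale);
* trend power: five pre-years at 2,000 patients/year with a planted
  treated-only +1 day/year trend in acute length, detected by the
  annual-family joint F-test.

Sizes were chosen so each study completes in minutes on one CPU while the
Monte-Carlo error stays well inside the margins being tested. Numerical
tie-breaks worth knowing: degenerate outcomes return a zero estimate with
a warning rather than failing; empty 2x2 cells raise an error naming the
cell; covariates constant within an analysis sample are dropped before
fitting; bootstrap replicates that lose all on-support controls return NA
and are excluded from the SE.

## 7. Known limitations

The linear probability DID can predict outside [0, 1] for extreme
covariate profiles; its effect estimate is still the quantity of interest.
Kernel matching with a fixed 0.06 bandwidth is inherited as the
conventional default, not tuned. The washout uses stay *overlap* with the
365-day window; registers that truncate stays at year boundaries would
need pre-chaining. And the generator's ground truth for cost outcomes is
indirect (through days), so cost-effect recovery is not part of the
calibration studies.
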