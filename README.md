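# strokebench

Register-based benchmarking of stroke care pathways with
difference-in-differences.

## The problem

When a city or region reorganizes stroke rehabilitation — opening a
dedicated interprofessional rehabilitation ward, adding a home-based
rehabilitation team — did its patients actually do better than they would
have under the old pathway? Randomization is rarely possible, but national
hospital discharge registers record every admission, transfer, and death.
`strokebench` implements the full analysis chain such a register-based
benchmarking study needs, for biostatisticians and health-services
researchers:

1. **Episode construction** (`build_episodes()`): chains consecutive
   hospital stays into each patient's *first institutional episode*
   (transfers on the same or next calendar day continue the episode,
   regardless of provider), selects one index stroke admission per patient
   and calendar year, resolves mixed stroke subtype codes by the severity
   hierarchy I60 (SAH) > I61 (ICH) > I63 (infarction) > I64 (ill-defined),
   and filters to incident ischaemic strokes: no stroke admission in the
   previous 365 days, no pre-index long-term care.
2. **Performance indicators** (`compute_indicators()`): per episode, the
   nine standard measures — acute and total episode length of stay, share
   discharged home and share institutionalized at 90 days (point-in-time
   occupancy among survivors), inpatient days within one year, 90-day and
   1-year mortality, and the per-diem-costed episode and 1-year inpatient
   cost (annual median cost per day per DRG-like cost group for acute care,
   specialty medians for psychiatry, standard daily rates otherwise).
3. **Effect estimation** (`fit_did_ols()`, `kernel_psm_did()`,
   `test_parallel_trends()`, `baseline_marginals()`): covariate-adjusted
   difference-in-differences on individual-level data. For treated group
   `T`, post period `P` and covariates `x` the linear model is

   `y_i = α + γ T_i + Σ_t δ_t 1[year_i = t] + τ (T_i × P_i) + β' x_i + ε_i`

   with the effect `τ` read off the interaction and HC1 robust standard
   errors (binary outcomes enter linearly; a nonlinear model inside the DID
   contrast does not identify the effect consistently). The first year
   after a reform is excluded as the implementation year. The common-trend
   assumption is probed on pre-period data by joint F-tests of
   region-by-time interactions (annual indicators and linear, logarithmic,
   quadratic trends), and a sensitivity analysis reweights controls by an
   Epanechnikov kernel on the propensity score (bandwidth 0.06) with
   bootstrapped standard errors.
4. **Rolling trends** (`build_trend_series()`): the figure methodology —
   refit the outcome-appropriate model (logistic / negative binomial /
   gamma log-link) on overlapping 365-day cohorts advanced by 30 days and
   report adjusted marginal estimates per region.
5. **Synthetic register** (`generate_register()`): a generator with known
   ground truth — regional baselines, secular trends, case-mix covariates,
   transfer chains, two-piece mortality, per-diem cost structure, and
   staged interventions whose configured effects are true DID effects on
   the indicator scale — so every estimator can be tested by parameter
   recovery.

## Worked example

The package ships a hand-built 20-patient register (`toy_register()`) that
exercises every cohort rule; its indicator values are hand-computed:

```r
library(strokebench)
toy <- toy_register()
be <- build_episodes(toy$stays, toy$patients, gap_days = 1, study_years = 2005)
be$log
#>            reason     n
#> 1:  non_ischaemic     3
#> 2:  recent_stroke     1
#> 3:  incomplete_id     0
#> 4: long_term_care     1
ind <- compute_indicators(be$episodes, be$stays, toy$patients, toy$ct)
ind[patient_id == "F11",
    .(acute_los, episode_los, institutionalized_90, inpatient_days_1y, cost_1y)]
#>    acute_los episode_los institutionalized_90 inpatient_days_1y cost_1y
#> 1:         9           9                 TRUE               179   30000
```

Of the 20 patients, 15 enter the ischaemic cohort: 3 leave through the
subtype hierarchy (one of them because a single ICH-coded stay inside an
infarction episode dominates it), 1 through the 365-day washout, 1 through
the long-term-care flag. Patient F11's 9-day acute episode is followed by a
nursing-home placement covering day 90, so they count as institutionalized,
with 179 inpatient days and a 1-year cost of 9 x 500 + 170 x 150 = 30,000
currency units.

The full analysis workflow lives under `analysis/`:

```sh
Rscript analysis/01_simulate.R    # synthetic register 2001-2019 + ground truth
Rscript analysis/02_episodes.R    # episode construction + exclusion log
Rscript analysis/03_indicators.R  # the nine indicators
Rscript analysis/04_did.R         # three DID comparisons, trends tests, kernel PSM
Rscript analysis/05_trends.R      # 220 rolling-cohort marginal series
```

Each step narrates what it found and writes its tables under `results/`.
Step 4 prints a consolidated report per comparison (baseline marginals,
trend verdicts, DID and kernel-matched DID with significance stars) that
can be read against the ground truth written by step 1.

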