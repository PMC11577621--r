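Package: strokebench
Title: Register-Based Benchmarking of Stroke Care Pathways with
    Difference-in-Differences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds first institutional episodes of care from patient-level
    hospital discharge records (transfer chaining, stroke subtype hierarchy,
    365-day washout, long-term-care exclusion), computes nine performance
    indicators with per-diem costing (lengths of stay, 90-day placement,
    inpatient days, mortality, episode and one-year costs), and estimates
    regional intervention effects by covariate-adjusted OLS
    difference-in-differences with parallel-trend diagnostics, kernel
    propensity-score-matched sensitivity analysis with bootstrapped standard
    errors, and rolling-cohort marginal-effect trend series. Includes a
    synthetic register generator with known ground-truth effects for
    parameter-recovery and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    MASS,
    sandwich,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
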