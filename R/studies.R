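#' @name calibration_studies
#' @title Monte-Carlo calibration studies
#'
#' @description
#' Self-contained simulation studies exercising the whole pipeline under
#' known ground truth: parameter recovery of injected intervention effects,
#' type-I error calibration of the plain and kernel-matched DID under a null
#' scenario, and power of the parallel-trend diagnostic against a planted
#' treated-only pre-trend. Each study fixes its scenario — the study
#' conditions — and takes only the number of replicates and a seed.
NULL

# Scenario of the recovery study: ~5,000 treated-region and ~50,000 control
# patients over 11 analysed cohort years, with the phased reform injecting
# -4.0 days on episode length and -5.1 percentage points on day-90
# institutionalization from 2006 on (2006 itself excluded from the fit as
# the implementation year).
recovery_scenario <- function(seed, n_per_year = 5000L) {
  scenario_config(
    n_patients_per_year = n_per_year, years = c(2001L, 2012L),
    region_shares = c(treated_city = 0.09, rest_treated_region = 0.01,
                      rest_country = 0.90),
    interventions = list(reform = list(
      regions = "treated_city", year = 2006L,
      effects = c(episode_mean = -4.0, p_inst90 = -0.051))),
    seed = seed)
}

#' Parameter-recovery study
#'
#' For each replicate, generates the recovery scenario register, runs
#' episode construction, indicators, and the covariate-adjusted OLS DID for
#' episode length and institutionalization, and records estimate and SE
#' against the injected truths (-4.0 days, -5.1 points).
#'
#' @param n_rep Number of replicates.
#' @param seed Base seed; replicate r uses `seed * 1000 + r`.
#' @param n_per_year Cohort size per year (default 5000).
#' @return data.table with one row per replicate: estimates, SEs, and
#'   within-2-SE coverage flags for both outcomes.
#' @export
study_recovery <- function(n_rep = 20L, seed = 1L, n_per_year = 5000L) {
  truth <- c(episode_los = -4.0, institutionalized_90 = -0.051)
  rows <- lapply(seq_len(n_rep), function(r) {
    cfg <- recovery_scenario(seed * 1000L + r, n_per_year)
    reg <- generate_register(cfg)
    be <- build_episodes(reg$stays, reg$patients, 1L, 2001:2012)
    ind <- compute_indicators(be$episodes, be$stays, reg$patients,
                              synthetic_cost_table(cfg))
    out <- lapply(names(truth), function(oc) {
      sp <- did_spec(oc, "treated_city", "rest_country", 2001:2005,
                     2007:2012, 2006L)
      fit_did_ols(ind, sp)
    })
    data.table::data.table(
      rep = r,
      episode_est = out[[1]]$estimate, episode_se = out[[1]]$se,
      inst_est = out[[2]]$estimate, inst_se = out[[2]]$se)
  })
  res <- data.table::rbindlist(rows)
  res[, episode_covered := abs(episode_est - truth[["episode_los"]]) <=
        2 * episode_se]
  res[, inst_covered := abs(inst_est - truth[["institutionalized_90"]]) <=
        2 * inst_se]
  res[]
}

# Null scenario of the calibration study: four cohort years, no intervention
# effects, modest per-year cohorts.
null_scenario <- function(seed, n_per_year = 100L) {
  scenario_config(
    n_patients_per_year = n_per_year, years = c(2001L, 2004L),
    region_shares = c(treated_city = 0.25, rest_treated_region = 0.05,
                      rest_country = 0.70),
    seed = seed)
}

#' Type-I error calibration of the DID estimators
#'
#' Under a null scenario (no injected effects), runs the full pipeline per
#' replicate and records the p-values of the plain OLS DID and of the
#' kernel-matched DID (bandwidth 0.06, bootstrapped SEs) for episode length,
#' plus the OLS estimate itself for the null-mean check.
#'
#' @param n_rep Number of replicates.
#' @param seed Base seed.
#' @param n_boot Bootstrap replicates for the kernel-matched DID
#'   (default 500).
#' @param n_per_year Cohort size per year.
#' @return data.table with `ols_p`, `psm_p`, `ols_est` per replicate.
#' @export
study_type1 <- function(n_rep = 200L, seed = 1L, n_boot = 500L,
                        n_per_year = 100L) {
  rows <- lapply(seq_len(n_rep), function(r) {
    cfg <- null_scenario(seed * 1000L + r, n_per_year)
    reg <- generate_register(cfg)
    be <- build_episodes(reg$stays, reg$patients, 1L, 2001:2004)
    ind <- compute_indicators(be$episodes, be$stays, reg$patients,
                              synthetic_cost_table(cfg))
    sp <- did_spec("episode_los", "treated_city", "rest_country",
                   2001:2002, 2003:2004)
    ols <- fit_did_ols(ind, sp)
    psm <- kernel_psm_did(ind, sp, bandwidth = 0.06, n_boot = n_boot,
                          seed = seed * 1000L + r)
    data.table::data.table(rep = r, ols_p = ols$p_value,
                           ols_est = ols$estimate, ols_se = ols$se,
                           psm_p = psm$p_value)
  })
  data.table::rbindlist(rows)
}

#' Power of the parallel-trend diagnostic against a planted pre-trend
#'
#' Plants a treated-city-only pre-trend of +1 day per year on acute length
#' of stay over five pre-intervention years (2,000 patients per year) and
#' records whether the joint interaction F-test of the annual-indicator
#' family rejects at the 5% level.
#'
#' @param n_rep Number of replicates.
#' @param seed Base seed.
#' @param n_per_year Cohort size per year (default 2000).
#' @param slope Planted treated-only trend, days per year (default 1).
#' @return Logical vector of rejections.
#' @export
study_trend_power <- function(n_rep = 100L, seed = 1L, n_per_year = 2000L,
                              slope = 1.0) {
  vapply(seq_len(n_rep), function(r) {
    cfg <- scenario_config(
      n_patients_per_year = n_per_year, years = c(2001L, 2005L),
      region_shares = c(treated_city = 0.30, rest_treated_region = 0.0,
                        rest_country = 0.70),
      region_trends = list(list(regions = "treated_city",
                                effects = c(acute_mean = slope))),
      seed = seed * 1000L + r)
    reg <- generate_register(cfg)
    be <- build_episodes(reg$stays, reg$patients, 1L, 2001:2005)
    ind <- compute_indicators(be$episodes, be$stays, reg$patients,
                              synthetic_cost_table(cfg))
    sp <- did_spec("acute_los", "treated_city", "rest_country", 2001:2005,
                   2006L)
    tt <- test_parallel_trends(ind, sp)
    attr(tt, "annual_p") < 0.05
  }, logical(1))
}

#' DID estimator versus the cell-mean oracle on random balanced designs
#'
#' Draws random balanced 2x2 datasets without covariates and compares
#' [fit_did_ols()] with the closed-form difference of cell-mean differences.
#'
#' @param n_datasets Number of random datasets.
#' @param seed Seed.
#' @return Largest absolute discrepancy observed.
#' @export
study_did_identity <- function(n_datasets = 1000L, seed = 1L) {
  set.seed(seed)
  sp <- did_spec("y", "treated_city", "rest_country", 2002L, 2008L,
                 covariates = character())
  worst <- 0
  for (i in seq_len(n_datasets)) {
    m <- sample(5:30, 1)
    treat <- rep(c(0, 0, 1, 1), each = m)
    post <- rep(c(0, 1, 0, 1), each = m)
    y <- rnorm(4 * m, mean = 10 * treat + 5 * post, sd = sample(1:5, 1))
    d <- data.table::data.table(
      y = y, region = ifelse(treat == 1, "treated_city", "rest_country"),
      cohort_year = ifelse(post == 1, 2008L, 2002L))
    cm <- tapply(y, list(treat, post), mean)
    oracle <- (cm["1", "1"] - cm["1", "0"]) - (cm["0", "1"] - cm["0", "0"])
    worst <- max(worst, abs(fit_did_ols(d, sp)$estimate - oracle))
  }
  worst
}
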