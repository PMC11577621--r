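#' Scenario configuration for the synthetic discharge register
#'
#' Defines the statistical structure of a generated patient/stay register:
#' regional baselines for the outcome-generating process, secular improvement
#' trends, staged interventions with known (ground-truth) effects, a case-mix
#' covariate model, the transfer-chain model, and per-diem cost structure.
#'
#' Regional baselines are expressed on the scale the performance indicators are
#' measured on: mean acute and episode length among 90-day survivors (days),
#' the unconditional probability of being institutionalized at day 90
#' (alive and in institutional care), and 90-day / 1-year mortality risks.
#' The share discharged home at 90 days is not a free parameter: with
#' point-in-time day-90 placement it is the survivor complement of
#' institutionalization.
#'
#' Interventions are lists with elements `regions` (subset of the region
#' names), `year` (first effective calendar year) and `effects`, a named
#' vector of additive shifts on any of `acute_mean`, `episode_mean`,
#' `p_inst90`, `p_dead90`, `p_dead1y`. These shifts are the true
#' difference-in-difference effects on the indicator scale and are returned as
#' ground truth by [generate_register()].
#'
#' @param n_patients_per_year Cohort size per calendar year.
#' @param years Length-2 integer vector `c(first_year, last_year)`.
#' @param region_shares Named proportions over `treated_city`,
#'   `rest_treated_region`, `rest_country`; must sum to 1.
#' @param baseline Named list per region, each a named vector with
#'   `acute_mean`, `episode_mean` (days), `p_inst90`, `p_dead90`, `p_dead1y`
#'   (probabilities).
#' @param secular_trend Named vector of additive annual drift applied to the
#'   baseline parameters in all regions (units of the parameter per year).
#' @param interventions List of intervention descriptors (see Details).
#' @param region_trends Optional list of region-specific pre-existing trends,
#'   each `list(regions=, effects=)` where effects are per-year slopes added
#'   as `slope * (year - first_year)`. Used to plant common-trend violations.
#' @param covariate_model Age distribution, sex proportion, 16 comorbidity
#'   prevalences and their coefficients on the log (lengths) and log-odds
#'   (placement, mortality) scales.
#' @param transfer_model Probabilities of splitting episode segments into
#'   chained transfer stays and of a 1-day transfer gap.
#' @param cost_model Per-diem rates: acute rate, cost-group multipliers,
#'   non-acute provider rates and the psychiatric per-diem.
#' @param dx_probs Distribution of the index stroke subtype over ICD-10 codes
#'   I60/I61/I63/I64.
#' @param ltc_rate Share of patients flagged as in long-term care before the
#'   index admission (excluded by the cohort filters).
#' @param readmit_rate Probability of an unrelated later acute readmission
#'   within the index year.
#' @param psych_rate Probability of a later psychiatric stay.
#' @param seed Integer seed; the whole register is a deterministic function of
#'   the configuration including the seed.
#' @return A validated object of class `scenario_config`.
#' @export
scenario_config <- function(n_patients_per_year = 1000L,
                            years = c(2001L, 2012L),
                            region_shares = c(treated_city = 0.02,
                                              rest_treated_region = 0.025,
                                              rest_country = 0.955),
                            baseline = default_baseline(),
                            secular_trend = c(acute_mean = -0.25,
                                              episode_mean = -0.30,
                                              p_inst90 = -0.002,
                                              p_dead90 = -0.0025,
                                              p_dead1y = -0.0035),
                            interventions = list(),
                            region_trends = list(),
                            covariate_model = default_covariate_model(),
                            transfer_model = list(p_split_acute = 0.35,
                                                  p_split_nonacute = 0.25,
                                                  p_gap1 = 0.2),
                            cost_model = default_cost_model(),
                            dx_probs = c(I63 = 0.86, I61 = 0.08,
                                         I60 = 0.03, I64 = 0.03),
                            ltc_rate = 0.01,
                            readmit_rate = 0.15,
                            psych_rate = 0.01,
                            seed = 1L) {
  cfg <- list(
    n_patients_per_year = as.integer(n_patients_per_year),
    years = as.integer(years),
    region_shares = region_shares,
    baseline = baseline,
    secular_trend = secular_trend,
    interventions = interventions,
    region_trends = region_trends,
    covariate_model = covariate_model,
    transfer_model = transfer_model,
    cost_model = cost_model,
    dx_probs = dx_probs,
    ltc_rate = ltc_rate,
    readmit_rate = readmit_rate,
    psych_rate = psych_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "scenario_config"
  validate_scenario(cfg)
}

#' @rdname scenario_config
#' @export
region_levels <- function() {
  c("treated_city", "rest_treated_region", "rest_country")
}

#' @rdname scenario_config
#' @export
default_baseline <- function() {
  list(
    treated_city = c(acute_mean = 11.7, episode_mean = 30.3,
                     p_inst90 = 0.168, p_dead90 = 0.159, p_dead1y = 0.236),
    rest_treated_region = c(acute_mean = 8.5, episode_mean = 27.2,
                            p_inst90 = 0.122, p_dead90 = 0.132,
                            p_dead1y = 0.198),
    rest_country = c(acute_mean = 12.2, episode_mean = 27.0,
                     p_inst90 = 0.115, p_dead90 = 0.145, p_dead1y = 0.213)
  )
}

#' @rdname scenario_config
#' @export
default_covariate_model <- function() {
  list(
    age_mean = 74, age_sd = 11, p_female = 0.5,
    comorb_prev = c(0.30, 0.25, 0.20, 0.18, 0.15, 0.12, 0.12, 0.10,
                    0.10, 0.08, 0.08, 0.06, 0.05, 0.05, 0.04, 0.03),
    # coefficients: age (per SD), female, then the 16 comorbidity flags
    beta_los = c(age = 0.10, female = 0.03,
                 rep(c(0.10, 0.07, 0.05, 0.03), each = 4L)),
    beta_inst = c(age = 0.60, female = 0.05,
                  rep(c(0.20, 0.15, 0.10, 0.05), each = 4L)),
    beta_death = c(age = 0.70, female = -0.05,
                   rep(c(0.25, 0.18, 0.12, 0.06), each = 4L))
  )
}

#' @rdname scenario_config
#' @export
default_cost_model <- function() {
  list(
    acute_day_rate = 500,
    cost_groups = c(C01 = 0.75, C02 = 0.90, C03 = 1.00, C04 = 1.20,
                    C05 = 1.45),
    provider_rates = c(health_centre = 200, nursing_home = 150,
                       other_longterm = 150),
    psychiatric_day_rate = 300
  )
}

validate_scenario <- function(cfg) {
  if (!inherits(cfg, "scenario_config")) stopf("not a scenario_config")
  if (length(cfg$years) != 2L || cfg$years[2] < cfg$years[1])
    stopf("invalid field 'years': need c(first, last) with last >= first")
  if (cfg$n_patients_per_year < 0L)
    stopf("invalid field 'n_patients_per_year': must be >= 0")
  sh <- cfg$region_shares
  if (!setequal(names(sh), region_levels()))
    stopf("invalid field 'region_shares': names must be %s",
          paste(region_levels(), collapse = ", "))
  if (abs(sum(sh) - 1) > 1e-9)
    stopf("invalid field 'region_shares': must sum to 1 (got %.12f)", sum(sh))
  if (any(sh < 0)) stopf("invalid field 'region_shares': negative share")
  need <- c("acute_mean", "episode_mean", "p_inst90", "p_dead90", "p_dead1y")
  for (r in region_levels()) {
    b <- cfg$baseline[[r]]
    if (is.null(b) || !all(need %in% names(b)))
      stopf("invalid field 'baseline': region %s must provide %s",
            r, paste(need, collapse = ", "))
    if (b[["acute_mean"]] <= 0 || b[["episode_mean"]] <= 0)
      stopf("invalid field 'baseline': lengths must be strictly positive (%s)", r)
    pr <- b[c("p_inst90", "p_dead90", "p_dead1y")]
    if (any(pr < 0 | pr > 1))
      stopf("invalid field 'baseline': probabilities outside [0,1] (%s)", r)
    if (b[["p_dead1y"]] < b[["p_dead90"]])
      stopf("invalid field 'baseline': p_dead1y < p_dead90 (%s)", r)
  }
  for (iv in cfg$interventions) {
    if (!all(c("regions", "year", "effects") %in% names(iv)))
      stopf("invalid field 'interventions': need regions, year, effects")
    if (!all(iv$regions %in% region_levels()))
      stopf("invalid field 'interventions': unknown region %s",
            paste(setdiff(iv$regions, region_levels()), collapse = ","))
    if (iv$year < cfg$years[1] || iv$year > cfg$years[2])
      stopf("invalid field 'interventions': effective_year %d outside year range",
            iv$year)
    if (!all(names(iv$effects) %in% need))
      stopf("invalid field 'interventions': unknown effect target %s",
            paste(setdiff(names(iv$effects), need), collapse = ","))
  }
  for (tv in cfg$region_trends) {
    if (!all(c("regions", "effects") %in% names(tv)))
      stopf("invalid field 'region_trends': need regions, effects")
    if (!all(tv$regions %in% region_levels()))
      stopf("invalid field 'region_trends': unknown region")
  }
  cm <- cfg$cost_model
  if (cm$acute_day_rate <= 0 || any(cm$cost_groups <= 0) ||
      any(cm$provider_rates <= 0) || cm$psychiatric_day_rate <= 0)
    stopf("invalid field 'cost_model': all rates must be strictly positive")
  if (abs(sum(cfg$dx_probs) - 1) > 1e-9 || any(cfg$dx_probs < 0))
    stopf("invalid field 'dx_probs': must be a probability distribution")
  for (f in c("ltc_rate", "readmit_rate", "psych_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stopf("invalid field '%s': must be in [0,1]", f)
  }
  cfg
}

# Per-cell (region x year) parameter targets after trends and interventions.
#
# Probability parameters carry intervention effects directly (they are
# targeted on the unconditional indicator scale). For the two length
# parameters the intervention effects are returned in separate columns
# (`eff_acute`, `eff_episode`): the generator injects them into the
# survivor-level draw scaled by 1 / P(alive at 90), so that the shift on the
# measured cohort-level indicator equals the configured effect.
scenario_cell_params <- function(cfg) {
  years <- seq(cfg$years[1], cfg$years[2])
  need <- c("acute_mean", "episode_mean", "p_inst90", "p_dead90", "p_dead1y")
  grid <- data.table::CJ(region = region_levels(), year = years)
  for (p in need) {
    base <- vapply(cfg$baseline, `[[`, numeric(1), p)[grid$region]
    drift <- (cfg$secular_trend[p] %||% 0)
    drift <- if (is.na(drift)) 0 else drift
    val <- base + drift * (grid$year - cfg$years[1])
    for (tv in cfg$region_trends) {
      eff <- tv$effects[p]
      if (!is.null(eff) && !is.na(eff)) {
        hit <- grid$region %in% tv$regions
        val[hit] <- val[hit] + eff * (grid$year[hit] - cfg$years[1])
      }
    }
    grid[[p]] <- val
  }
  grid$eff_acute <- 0
  grid$eff_episode <- 0
  for (iv in cfg$interventions) {
    hit <- grid$region %in% iv$regions & grid$year >= iv$year
    for (p in names(iv$effects)) {
      eff <- iv$effects[[p]]
      if (p == "acute_mean") grid$eff_acute[hit] <- grid$eff_acute[hit] + eff
      else if (p == "episode_mean")
        grid$eff_episode[hit] <- grid$eff_episode[hit] + eff
      else grid[[p]][hit] <- grid[[p]][hit] + eff
    }
  }
  # keep probabilities and lengths in their domains after drift stacking
  grid$p_inst90 <- pmin(pmax(grid$p_inst90, 0), 1)
  grid$p_dead90 <- pmin(pmax(grid$p_dead90, 0), 1)
  grid$p_dead1y <- pmin(pmax(grid$p_dead1y, grid$p_dead90), 1)
  grid$acute_mean <- pmax(grid$acute_mean, 0.5)
  grid$episode_mean <- pmax(grid$episode_mean, 1)
  data.table::setkeyv(grid, c("region", "year"))
  grid[]
}

# Ground-truth table: one row per configured intervention x affected outcome,
# effects on the natural indicator scale.
scenario_ground_truth <- function(cfg) {
  if (!length(cfg$interventions)) {
    return(data.table::data.table(intervention = character(),
                                  regions = character(), year = integer(),
                                  outcome = character(), effect = numeric()))
  }
  out <- lapply(seq_along(cfg$interventions), function(i) {
    iv <- cfg$interventions[[i]]
    nm <- names(cfg$interventions)[i]
    if (is.null(nm) || is.na(nm) || nm == "") nm <- paste0("intervention_", i)
    data.table::data.table(
      intervention = nm,
      regions = paste(iv$regions, collapse = "+"),
      year = as.integer(iv$year),
      outcome = names(iv$effects),
      effect = as.numeric(iv$effects)
    )
  })
  data.table::rbindlist(out)
}
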