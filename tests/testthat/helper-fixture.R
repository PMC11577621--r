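# Shared fixtures: the hand-built 20-patient register lives in the package
# (toy_register()); these wrappers keep the test files terse.

fixture_stays <- function() toy_register()$stays
fixture_patients <- function() toy_register()$patients
fixture_cost_table <- function() toy_register()$ct
fixture_expected_indicators <- function() toy_register()$expected

# small scenario used across tests; region shares give usable cell sizes
test_scenario <- function(n_per_year = 300, years = c(2001, 2004),
                          interventions = list(), seed = 1, ...) {
  scenario_config(
    n_patients_per_year = n_per_year, years = years,
    region_shares = c(treated_city = 0.25, rest_treated_region = 0.05,
                      rest_country = 0.70),
    interventions = interventions, seed = seed, ...)
}

run_small_pipeline <- function(cfg) {
  reg <- generate_register(cfg)
  be <- build_episodes(reg$stays, reg$patients, 1L,
                       seq(cfg$years[1], cfg$years[2]))
  ind <- compute_indicators(be$episodes, be$stays, reg$patients,
                            synthetic_cost_table(cfg))
  list(reg = reg, be = be, ind = ind)
}
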