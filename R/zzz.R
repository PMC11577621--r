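.datatable.aware <- TRUE

# data.table non-standard evaluation columns
utils::globalVariables(c(
  ".", "..cols", ".cm", ".new", ".stroke", "acute_end_date", "acute_los",
  "admit_date", "age", "birth_date", "chain_id", "cohort_year", "cost_1y",
  "cost_group", "d90", "death_date", "died_1y", "died_90", "disch_eff",
  "discharge_date", "dominant_dx", "episode_cost", "episode_end_date",
  "episode_los", "exclusion_reason", "home_90", "i.chain_id",
  "incomplete_id", "index_date", "index_dx", "inpatient_days_1y",
  "institutionalized_90", "lt", "main_dx", "mu_ac", "mu_ep", "m_los",
  "occupied_90", "p1yi", "p90i", "p_dead1y", "p_dead90", "p_inst90",
  "p_late", "patient_id", "pinsti", "pre_index_ltc", "prior_stroke",
  "provider_type", "rate", "recent_prior_stroke", "region", "regionf",
  "sex", "specialty", "t2", "treat", "verdict", "x.rate", "yearf",
  "eta_los", "eta_inst", "eta_death", "eff_acute", "eff_episode",
  "acute_mean", "episode_mean", "inst_90", "inst_target", "days",
  "cost", "year", "p_value", "i.index_date", "n_stays",
  ".rk", ".idx", ".ai", ".di", ".nonac", ".ep_end", ".ac_end",
  "ai", "di", "ii", "a1", "d1", "occf", "epcost", "yrcost", "cmprev",
  "contrib", "n_occ", "death_offset", "ep_chain", "epdays", "yrdays",
  "episode_est", "episode_se", "inst_est", "inst_se", "episode_covered",
  "inst_covered"
))
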