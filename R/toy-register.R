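#' A hand-built 20-patient example register
#'
#' A small synthetic register constructed by hand to exercise every cohort
#' rule at least once: same-day and next-day transfer chains, a chain broken
#' by a 2-day gap, the subtype hierarchy (an ICH-coded stay inside an
#' infarction episode, a pure SAH, a pure ill-defined stroke), a prior
#' stroke inside the 365-day washout and another beyond it, a pre-index
#' long-term-care flag, death during and after the episode, day-90
#' institutionalization through the episode itself and through a later
#' placement, overlapping duplicate-style stays, a psychiatric tail stay, a
#' later unrelated readmission, a window-clipped nursing stay, same-day
#' discharge, and an unknown cost group hitting the fallback rate.
#'
#' `expected` holds the hand-computed indicator values for the 15 patients
#' that survive the cohort filters (for 2005 as the study year), so the
#' register doubles as an end-to-end worked example.
#'
#' @return List with `patients`, `stays`, `ct` (a matching [cost_table()]:
#'   C01 at 500/day, C02 at 300/day, all-acute fallback 400/day, health
#'   centre 200, nursing home 150, other long-term 175, psychiatry 250),
#'   and `expected` (hand-computed indicator rows).
#' @export
toy_register <- function() {
  row <- function(pid, a, d, prov, ptype, spec, dx, cg) {
    data.table::data.table(patient_id = pid, admit_date = as.Date(a),
                           discharge_date = as.Date(d), provider_id = prov,
                           provider_type = ptype, specialty = spec,
                           main_dx = dx, cost_group = cg)
  }
  stays <- data.table::rbindlist(list(
    row("F01", "2005-03-01", "2005-03-11", "H1", "acute_hospital", "15", "I639", "C01"),
    row("F02", "2005-04-01", "2005-04-08", "H1", "acute_hospital", "15", "I630", "C01"),
    row("F02", "2005-04-08", "2005-05-10", "HC1", "health_centre", "98", "I630", NA),
    row("F03", "2005-05-01", "2005-05-06", "H1", "acute_hospital", "15", "I631", "C01"),
    row("F03", "2005-05-07", "2005-07-01", "NH1", "nursing_home", "98", "I631", NA),
    row("F04", "2005-06-01", "2005-06-10", "H1", "acute_hospital", "15", "I634", "C02"),
    row("F04", "2005-06-12", "2005-06-20", "H2", "acute_hospital", "15", "I634", "C02"),
    row("F05", "2005-02-01", "2005-02-15", "H1", "acute_hospital", "15", "I630", "C01"),
    row("F05", "2005-02-15", "2005-02-20", "H1", "acute_hospital", "15", "I611", "C01"),
    row("F06", "2005-01-10", "2005-01-30", "H1", "acute_hospital", "15", "I609", "C01"),
    row("F07", "2004-12-01", "2004-12-10", "H1", "acute_hospital", "15", "I639", "C01"),
    row("F07", "2005-03-15", "2005-03-25", "H1", "acute_hospital", "15", "I630", "C01"),
    row("F08", "2004-01-01", "2004-01-08", "H1", "acute_hospital", "15", "I639", "C01"),
    row("F08", "2005-06-01", "2005-06-12", "H1", "acute_hospital", "15", "I633", "C01"),
    row("F09", "2005-07-01", "2005-07-15", "H1", "acute_hospital", "15", "I630", "C01"),
    row("F10", "2005-08-01", "2005-08-21", "H1", "acute_hospital", "15", "I630", "C01"),
    row("F11", "2005-09-01", "2005-09-10", "H1", "acute_hospital", "15", "I630", "C01"),
    row("F11", "2005-09-12", "2006-03-01", "NH1", "nursing_home", "98", "I69", NA),
    row("F12", "2005-10-01", "2005-10-15", "H1", "acute_hospital", "15", "I630", "C01"),
    row("F12", "2005-10-15", "2006-02-01", "HC1", "health_centre", "98", "I630", NA),
    row("F13", "2005-03-10", "2005-03-20", "H1", "acute_hospital", "15", "I630", "C02"),
    row("F14", "2005-04-15", "2005-04-15", "H1", "acute_hospital", "15", "I630", "C01"),
    row("F15", "2005-05-20", "2005-06-10", "H1", "acute_hospital", "15", "I630", "C01"),
    row("F15", "2005-05-25", "2005-06-05", "H2", "acute_hospital", "15", "I630", "C01"),
    row("F16", "2005-06-15", "2005-06-25", "H1", "acute_hospital", "15", "I630", "C01"),
    row("F16", "2005-06-25", "2005-07-15", "PS1", "psychiatric", "70", "F03", NA),
    row("F17", "2005-07-20", "2005-07-30", "H1", "acute_hospital", "15", "I64", "C01"),
    row("F18", "2005-02-10", "2005-02-20", "H1", "acute_hospital", "15", "I630", "C02"),
    row("F18", "2005-11-01", "2005-11-11", "H1", "acute_hospital", "10", "J18", "C01"),
    row("F19", "2005-01-15", "2005-01-25", "H1", "acute_hospital", "15", "I630", "C01"),
    row("F19", "2005-12-01", "2006-03-01", "NH1", "nursing_home", "98", "I69", NA),
    row("F20", "2005-03-05", "2005-03-15", "H1", "acute_hospital", "15", "I630", "C9")
  ))

  patients <- data.table::data.table(
    patient_id = sprintf("F%02d", 1:20),
    birth_date = as.Date("1935-06-15"),
    sex = rep(c("female", "male"), 10),
    region = rep(c("treated_city", "rest_treated_region", "rest_country"),
                 length.out = 20),
    death_date = as.Date(NA))
  patients[patient_id == "F10", death_date := as.Date("2005-08-15")]
  patients[patient_id == "F13", death_date := as.Date("2005-09-26")]
  for (j in sprintf("cb%02d", 1:16)) patients[[j]] <- FALSE
  patients$pre_index_ltc <- patients$patient_id == "F09"

  acute <- data.table::CJ(cost_group = c("C01", "C02"), year = 2004:2006)
  acute[, rate := ifelse(cost_group == "C01", 500, 300)]
  ct <- cost_table(acute,
                   provider_rates = c(health_centre = 200,
                                      nursing_home = 150,
                                      other_longterm = 175),
                   acute_fallback = data.table::data.table(year = 2004:2006,
                                                           rate = 400),
                   psychiatric = 250)

  e <- function(pid, acute, ep, home, inst, days, d90, d1y, epc, c1y, prior) {
    data.table::data.table(patient_id = pid, acute_los = acute,
                           episode_los = ep, home_90 = home,
                           institutionalized_90 = inst,
                           inpatient_days_1y = days, died_90 = d90,
                           died_1y = d1y, episode_cost = epc, cost_1y = c1y,
                           prior_stroke = prior)
  }
  expected <- data.table::rbindlist(list(
    e("F01", 10L, 10L, TRUE, FALSE, 10L, FALSE, FALSE, 5000, 5000, FALSE),
    e("F02", 7L, 39L, TRUE, FALSE, 39L, FALSE, FALSE, 9900, 9900, FALSE),
    e("F03", 5L, 61L, TRUE, FALSE, 60L, FALSE, FALSE, 10750, 10750, FALSE),
    e("F04", 9L, 9L, TRUE, FALSE, 17L, FALSE, FALSE, 2700, 5100, FALSE),
    e("F08", 11L, 11L, TRUE, FALSE, 11L, FALSE, FALSE, 5500, 5500, TRUE),
    e("F10", 14L, 14L, FALSE, FALSE, 14L, TRUE, TRUE, 7000, 7000, FALSE),
    e("F11", 9L, 9L, FALSE, TRUE, 179L, FALSE, FALSE, 4500, 30000, FALSE),
    e("F12", 14L, 123L, FALSE, TRUE, 123L, FALSE, FALSE, 28800, 28800, FALSE),
    e("F13", 10L, 10L, TRUE, FALSE, 10L, FALSE, TRUE, 3000, 3000, FALSE),
    e("F14", 1L, 1L, TRUE, FALSE, 1L, FALSE, FALSE, 500, 500, FALSE),
    e("F15", 21L, 21L, TRUE, FALSE, 21L, FALSE, FALSE, 16000, 16000, FALSE),
    e("F16", 10L, 30L, TRUE, FALSE, 30L, FALSE, FALSE, 10000, 10000, FALSE),
    e("F18", 10L, 10L, TRUE, FALSE, 20L, FALSE, FALSE, 3000, 8000, FALSE),
    e("F19", 10L, 10L, TRUE, FALSE, 55L, FALSE, FALSE, 5000, 11750, FALSE),
    e("F20", 10L, 10L, TRUE, FALSE, 10L, FALSE, FALSE, 4000, 4000, FALSE)
  ))

  list(patients = patients, stays = stays, ct = ct, expected = expected)
}
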