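#' @name indicators
#' @title Performance indicators per episode
#'
#' @description
#' Nine per-patient measures summarize each first institutional episode:
#' length of the first acute-care admission and of the whole episode (days),
#' discharge home and institutionalization at 90 days, inpatient days within
#' one year, 90-day and 1-year mortality, and the per-diem-costed episode and
#' one-year inpatient costs. Day counts use the floor-1 convention (same-day
#' discharge counts as one day); death truncates lengths, day counts and cost
#' accrual.
NULL

#' Episode lengths
#'
#' @param index_date,acute_end_date,episode_end_date Episode dates
#'   (vectorized).
#' @param death_date Optional death dates; death during the episode truncates
#'   both lengths.
#' @return data.table with `acute_los` and `episode_los` in days (floor 1).
#' @export
compute_lengths <- function(index_date, acute_end_date, episode_end_date,
                            death_date = NULL) {
  if (is.null(death_date)) death_date <- as.Date(rep(NA, length(index_date)))
  ae <- data.table::fifelse(!is.na(death_date) & death_date < acute_end_date,
                            death_date, acute_end_date)
  ee <- data.table::fifelse(!is.na(death_date) & death_date < episode_end_date,
                            death_date, episode_end_date)
  data.table::data.table(acute_los = days_len(index_date, ae),
                         episode_los = days_len(index_date, ee))
}

#' Mortality flags
#'
#' @param index_date,death_date Date vectors (`death_date` NA for survivors).
#' @return data.table with `died_90` (death within 90 days of the index) and
#'   `died_1y` (within 365 days).
#' @export
mortality_flags <- function(index_date, death_date) {
  if (any(!is.na(death_date) & death_date < index_date))
    stopf("death_date before index_date")
  off <- as.integer(death_date) - as.integer(index_date)
  data.table::data.table(died_90 = !is.na(off) & off <= 90L,
                         died_1y = !is.na(off) & off <= 365L)
}

#' Day-90 placement of one patient
#'
#' By default placement is point-in-time occupancy on day 90 after the index:
#' a surviving patient is institutionalized when some institutional stay
#' covers day 90, and discharged home when no stay covers day 90 and the
#' first episode ended by then; the two are mutually exclusive and patients
#' dead by day 90 get neither. The alternative `"ever_discharged"` rule
#' marks home when the episode ended within 90 days and the patient survived,
#' regardless of day-90 occupancy.
#'
#' @param episode One episode (list or one-row table) with `index_date` and
#'   `episode_end_date`.
#' @param stays The patient's stays.
#' @param death_date Death date or NA.
#' @param rule `"point_in_time"` (default) or `"ever_discharged"`.
#' @return Named logical vector `c(home_90=, institutionalized_90=)`.
#' @export
placement_at_90 <- function(episode, stays, death_date = NA,
                            rule = c("point_in_time", "ever_discharged")) {
  rule <- match.arg(rule)
  st <- data.table::as.data.table(stays)
  idx <- as.Date(episode$index_date)
  d90 <- idx + 90L
  alive90 <- is.na(death_date) || as.Date(death_date) > d90
  if (!alive90)
    return(c(home_90 = FALSE, institutionalized_90 = FALSE))
  disch <- st$discharge_date
  if (!is.na(death_date)) disch <- pmin(disch, as.Date(death_date))
  occupied <- nrow(st) > 0 &&
    any(st$admit_date <= d90 & pmax(disch, st$admit_date + 1L) > d90)
  ep_end <- as.Date(episode$episode_end_date)
  if (!is.na(death_date)) ep_end <- min(ep_end, as.Date(death_date))
  home <- if (rule == "point_in_time") !occupied && ep_end <= d90
          else ep_end <= d90
  c(home_90 = home, institutionalized_90 = occupied)
}

#' Inpatient days within one year of the index
#'
#' Total days spent in any institutional stay within `[index, index + 365)`,
#' with overlapping stays merged before counting, same-day stays widened to
#' one day, truncation at death, and a cap at 365.
#'
#' @param stays The patient's stays.
#' @param index_date Index admission date.
#' @param death_date Death date or NA.
#' @return Integer days in `[0, 365]`.
#' @export
inpatient_days_1y <- function(stays, index_date, death_date = NA) {
  st <- data.table::as.data.table(stays)
  if (nrow(st) == 0L) return(0L)
  disch <- st$discharge_date
  if (!is.na(death_date)) disch <- pmin(disch, as.Date(death_date))
  keep <- disch >= st$admit_date  # stays entirely after death accrue nothing
  if (!any(keep)) return(0L)
  d <- interval_union_days(st$admit_date[keep], disch[keep], index_date,
                           as.Date(index_date) + 365L)
  min(365L, d)
}

#' Compute the full indicator table
#'
#' Joins included episodes with patient demographics and stays, and computes
#' the nine performance indicators plus the risk-adjustment covariates
#' (age at index, sex, 16 comorbidity flags, previous-stroke flag) for each
#' episode.
#'
#' @param episodes Included episodes from [build_episodes()].
#' @param stays Chained stay table.
#' @param patients Patient table.
#' @param ct A [cost_table()].
#' @param home_rule Day-90 home-discharge rule, see [placement_at_90()].
#' @return data.table with one row per episode (`IndicatorRow`): identifiers
#'   and cohort labels, the nine indicators, and covariates.
#' @export
compute_indicators <- function(episodes, stays, patients, ct,
                               home_rule = c("point_in_time",
                                             "ever_discharged")) {
  home_rule <- match.arg(home_rule)
  ep <- data.table::as.data.table(episodes)
  st <- data.table::as.data.table(stays)
  pt <- data.table::as.data.table(patients)
  if (nrow(ep) == 0L) return(empty_indicators())

  cb <- grep("^cb[0-9]{2}$", names(pt), value = TRUE)
  out <- pt[, c("patient_id", "birth_date", "sex", "region", "death_date",
                cb), with = FALSE][ep, on = "patient_id"]
  if (any(!is.na(out$death_date) & out$death_date < out$index_date))
    stopf("death_date before index_date")
  out[, age := floor(as.numeric(index_date - birth_date) / 365.25)]

  len <- compute_lengths(out$index_date, out$acute_end_date,
                         out$episode_end_date, out$death_date)
  out[, `:=`(acute_los = len$acute_los, episode_los = len$episode_los)]
  mf <- mortality_flags(out$index_date, out$death_date)
  out[, `:=`(died_90 = mf$died_90, died_1y = mf$died_1y)]

  # per-episode stay scan: day-90 occupancy, 1-year day union, window costs
  # (all of the patient's stays, not only the episode's own chain)
  eps <- out[, .(patient_id, ep_chain = chain_id, index_date, episode_los,
                 death_date)]
  ss <- st[, .(patient_id, admit_date, discharge_date, provider_type,
               specialty, cost_group)][eps, on = "patient_id",
                                       allow.cartesian = TRUE]
  ss[, disch_eff := data.table::fifelse(
      !is.na(death_date) & death_date < discharge_date,
      death_date, discharge_date)]
  ss <- ss[disch_eff >= admit_date]
  ss[, rate := stay_day_rates(ct, provider_type, cost_group, specialty,
                              year_of(admit_date))]
  # fully vectorized stay scan (same-day stays widened to one day)
  ss[, `:=`(ai = as.integer(admit_date),
            di = pmax(as.integer(disch_eff), as.integer(admit_date) + 1L),
            ii = as.integer(index_date))]
  ss[, occf := ai <= ii + 90L & di > ii + 90L]
  ss[, epcost := pmax(0L, pmin(di, ii + episode_los) - pmax(ai, ii)) * rate]
  ss[, yrcost := pmax(0L, pmin(di, ii + 365L) - pmax(ai, ii)) * rate]
  # merged-interval day count inside [index, index+365)
  ss[, `:=`(a1 = pmax(ai, ii), d1 = pmin(di, ii + 365L))]
  data.table::setorder(ss, patient_id, ep_chain, ai, di)
  ss[, cmprev := data.table::shift(cummax(d1)), by = .(patient_id, ep_chain)]
  ss[, contrib := pmax(0L, d1 - pmax(a1, data.table::fcoalesce(cmprev, 0L)))]
  scan <- ss[, .(n_occ = sum(occf), inpatient_days_1y = sum(contrib),
                 episode_cost = sum(epcost), cost_1y = sum(yrcost)),
             by = .(patient_id, ep_chain)]
  scan[, occupied_90 := n_occ > 0L]
  scan[, inpatient_days_1y := pmin(365L, inpatient_days_1y)]
  scan[, n_occ := NULL]
  data.table::setnames(scan, "ep_chain", "chain_id")
  out <- scan[out, on = c("patient_id", "chain_id")]
  out[is.na(occupied_90), `:=`(occupied_90 = FALSE, inpatient_days_1y = 0L,
                               episode_cost = 0, cost_1y = 0)]

  alive90 <- is.na(out$death_date) | out$death_date > out$index_date + 90L
  ep_end_eff <- out$index_date + out$episode_los
  ended_by_90 <- out$episode_los <= 90L & ep_end_eff <= out$index_date + 90L
  out[, institutionalized_90 := alive90 & occupied_90]
  if (home_rule == "point_in_time") {
    out[, home_90 := alive90 & !occupied_90 & ended_by_90]
  } else {
    out[, home_90 := alive90 & ended_by_90]
  }

  cols <- c("patient_id", "cohort_year", "region", "index_date",
            "acute_los", "episode_los", "home_90", "institutionalized_90",
            "inpatient_days_1y", "died_90", "died_1y",
            "episode_cost", "cost_1y", "age", "sex", cb, "prior_stroke")
  out[, ..cols]
}

empty_indicators <- function() {
  di <- data.table::data.table(
    patient_id = character(), cohort_year = integer(), region = character(),
    index_date = as.Date(character()), acute_los = integer(),
    episode_los = integer(), home_90 = logical(),
    institutionalized_90 = logical(), inpatient_days_1y = integer(),
    died_90 = logical(), died_1y = logical(), episode_cost = numeric(),
    cost_1y = numeric(), age = numeric(), sex = character())
  for (j in sprintf("cb%02d", 1:16)) di[[j]] <- logical()
  di$prior_stroke <- logical()
  di
}

#' Default risk-adjustment covariates
#'
#' Age at index, sex, the 16 comorbidity flags and the previous-stroke flag.
#'
#' @return Character vector of column names in the indicator table.
#' @export
default_covariates <- function() {
  c("age", "sex", sprintf("cb%02d", 1:16), "prior_stroke")
}
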