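#' Per-diem cost table
#'
#' Inpatient care is converted to money at a single reference price level
#' using per-day rates: acute-hospital days are priced by the annual median
#' cost per day of their cost group (a DRG-like code), with the all-acute
#' annual median as fallback for groups without data; psychiatric days by the
#' specialty's median per diem; all other institutional days (health centre,
#' nursing home, other long-term care) by standard per-day rates.
#'
#' @param acute data.table/data.frame with columns `cost_group`, `year`,
#'   `rate` (currency per day).
#' @param provider_rates Named numeric vector with entries `health_centre`,
#'   `nursing_home`, `other_longterm`.
#' @param acute_fallback data.table with `year`, `rate`: the all-acute annual
#'   median used when a (cost_group, year) rate is missing.
#' @param psychiatric Either a single per-diem rate or a data.table with
#'   `specialty`, `year`, `rate`.
#' @return Object of class `cost_table`.
#' @export
cost_table <- function(acute, provider_rates, acute_fallback,
                       psychiatric = NULL) {
  acute <- data.table::as.data.table(acute)
  acute_fallback <- data.table::as.data.table(acute_fallback)
  stopifnot(all(c("cost_group", "year", "rate") %in% names(acute)),
            all(c("year", "rate") %in% names(acute_fallback)))
  need <- c("health_centre", "nursing_home", "other_longterm")
  if (!all(need %in% names(provider_rates)))
    stopf("provider_rates must name %s", paste(need, collapse = ", "))
  if (any(acute$rate <= 0) || any(acute_fallback$rate <= 0) ||
      any(provider_rates <= 0))
    stopf("all cost rates must be strictly positive")
  psych_tab <- NULL
  psych_rate <- NA_real_
  if (!is.null(psychiatric)) {
    if (is.numeric(psychiatric) && length(psychiatric) == 1L) {
      if (psychiatric <= 0) stopf("psychiatric rate must be positive")
      psych_rate <- psychiatric
    } else {
      psych_tab <- data.table::as.data.table(psychiatric)
      stopifnot(all(c("specialty", "year", "rate") %in% names(psych_tab)))
      if (any(psych_tab$rate <= 0)) stopf("psychiatric rates must be positive")
      psych_rate <- stats::median(psych_tab$rate)
    }
  }
  structure(list(acute = acute, acute_fallback = acute_fallback,
                 provider_rates = provider_rates, psych = psych_tab,
                 psych_rate = psych_rate),
            class = "cost_table")
}

#' Annual median cost per day from admission-level costs
#'
#' For each (cost group, year) with admission-level data, the per-diem rate
#' is the median over admissions of admission cost / admission days; the
#' even-count median is the mean of the two middle values. Groups without
#' data in a year fall back to the annual median over all acute admissions.
#'
#' @param admissions data.table with `cost_group`, `year`, `cost`, `days`.
#' @param provider_rates Standard per-day rates for non-acute care, passed to
#'   [cost_table()].
#' @param psychiatric Optional psychiatric per-diem (rate or table).
#' @return A [cost_table()].
#' @export
median_cost_per_day <- function(admissions, provider_rates,
                                psychiatric = NULL) {
  adm <- data.table::as.data.table(admissions)
  if (nrow(adm) == 0L) stopf("no admission-level cost data")
  stopifnot(all(c("cost_group", "year", "cost", "days") %in% names(adm)))
  adm <- adm[days > 0]
  acute <- adm[, .(rate = stats::median(cost / days)),
               by = .(cost_group, year)]
  fallback <- adm[, .(rate = stats::median(cost / days)), by = year]
  cost_table(acute = acute, provider_rates = provider_rates,
             acute_fallback = fallback, psychiatric = psychiatric)
}

#' Cost table consistent with a synthetic scenario's cost model
#'
#' @param config A [scenario_config()].
#' @param years Years to tabulate (default the scenario's range, widened by
#'   one year at each end so post-episode stays crossing year boundaries can
#'   always be priced).
#' @return A [cost_table()].
#' @export
synthetic_cost_table <- function(config, years = NULL) {
  cm <- config$cost_model
  if (is.null(years))
    years <- seq(config$years[1] - 1L, config$years[2] + 2L)
  acute <- data.table::CJ(cost_group = names(cm$cost_groups), year = years)
  acute[, rate := cm$acute_day_rate * cm$cost_groups[cost_group]]
  fb <- data.table::data.table(year = years, rate = cm$acute_day_rate)
  cost_table(acute = acute, provider_rates = cm$provider_rates,
             acute_fallback = fb, psychiatric = cm$psychiatric_day_rate)
}

# Vectorized per-diem rate for stays. Errors name the missing lookup.
stay_day_rates <- function(ct, provider_type, cost_group, specialty, year) {
  n <- length(provider_type)
  rate <- rep(NA_real_, n)

  is_ac <- provider_type == "acute_hospital"
  if (any(is_ac)) {
    q <- data.table::data.table(cost_group = cost_group[is_ac],
                                year = year[is_ac])
    r <- ct$acute[q, on = c("cost_group", "year"), x.rate]
    miss <- is.na(r)
    if (any(miss)) {
      fb <- ct$acute_fallback[data.table::data.table(year = q$year[miss]),
                              on = "year", x.rate]
      if (anyNA(fb)) {
        bad <- which(miss)[is.na(fb)][1L]
        stopf("no cost rate for cost_group %s in year %d",
              q$cost_group[bad] %||% "NA", q$year[bad])
      }
      r[miss] <- fb
    }
    rate[is_ac] <- r
  }

  is_ps <- provider_type == "psychiatric"
  if (any(is_ps)) {
    r <- rep(ct$psych_rate, sum(is_ps))
    if (!is.null(ct$psych)) {
      q <- data.table::data.table(specialty = specialty[is_ps],
                                  year = year[is_ps])
      rt <- ct$psych[q, on = c("specialty", "year"), x.rate]
      r[!is.na(rt)] <- rt[!is.na(rt)]
    }
    if (anyNA(r)) stopf("no psychiatric per-diem rate configured")
    rate[is_ps] <- r
  }

  other <- !is_ac & !is_ps
  if (any(other)) {
    r <- ct$provider_rates[provider_type[other]]
    if (anyNA(r))
      stopf("no per-diem rate for provider type '%s'",
            provider_type[other][is.na(r)][1L])
    rate[other] <- r
  }
  rate
}

#' Cost of stays over a window
#'
#' Sums, over the given stays, days inside the half-open window
#' `[window_start, window_end)` times the stay's per-diem rate (cost-group
#' median for acute care, specialty median for psychiatry, standard provider
#' rate otherwise). Days after death accrue no cost. Same-day stays count as
#' one day; each stay is billed separately, so overlapping stays are both
#' charged, mirroring per-admission invoicing.
#'
#' @param stays Stay table.
#' @param ct A [cost_table()].
#' @param window_start,window_end Window dates (end exclusive).
#' @param death_date Optional death date truncating accrual.
#' @return Total cost (currency units).
#' @export
cost_stays <- function(stays, ct, window_start, window_end,
                       death_date = NULL) {
  st <- data.table::as.data.table(stays)
  if (nrow(st) == 0L) return(0)
  disch <- st$discharge_date
  if (!is.null(death_date) && !is.na(death_date))
    disch <- pmin(disch, as.Date(death_date))
  keep <- disch >= st$admit_date  # stays entirely after death accrue nothing
  if (!any(keep)) return(0)
  st <- st[keep]
  days <- stay_days_window(st$admit_date, disch[keep], window_start,
                           window_end)
  rate <- stay_day_rates(ct, st$provider_type, st$cost_group, st$specialty,
                         year_of(st$admit_date))
  sum(days * rate)
}
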