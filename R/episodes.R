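#' @name episode_construction
#' @title Episode construction from raw hospital stays
#'
#' @description
#' A patient's *first institutional episode* is the maximal chain of
#' consecutive institutional stays starting at the index stroke admission,
#' with hospital transfers (admission on the same or next calendar day, by
#' default) continuing the chain regardless of provider. One candidate
#' episode is formed per patient and calendar year from the first
#' stroke-coded chain beginning in that year; cohort filters then keep
#' incident ischaemic strokes only.
NULL

stroke_prefixes <- c("I60", "I61", "I63", "I64")

is_stroke_code <- function(dx) {
  substr(dx, 1L, 3L) %in% stroke_prefixes
}

#' Resolve the dominant stroke subtype of an episode
#'
#' When an episode contains several stroke subtype codes, the most severe
#' is chosen, in the order subarachnoid haemorrhage (I60) > intracerebral
#' haemorrhage (I61) > cerebral infarction (I63) > ill-defined stroke (I64).
#' Codes are matched on their 3-character ICD-10 prefix.
#'
#' @param dx_codes Character vector of ICD-10 codes present in the episode.
#' @return One of `"SAH"`, `"ICH"`, `"infarction"`, `"ill_defined"`.
#' @export
resolve_dominant_dx <- function(dx_codes) {
  pre <- substr(dx_codes, 1L, 3L)
  if ("I60" %in% pre) return("SAH")
  if ("I61" %in% pre) return("ICH")
  if ("I63" %in% pre) return("infarction")
  if ("I64" %in% pre) return("ill_defined")
  stopf("no stroke code among: %s", paste(unique(dx_codes), collapse = ", "))
}

# vectorized variant over a grouping: dominant subtype per group
dominant_from_prefixes <- function(pre) {
  rank <- match(pre, stroke_prefixes)
  rank <- rank[!is.na(rank)]
  if (!length(rank)) return(NA_character_)
  c("SAH", "ICH", "infarction", "ill_defined")[min(rank)]
}

#' Chain consecutive stays of one patient into episodes of care
#'
#' Two stays belong to the same chain when the next admission is at most
#' `gap_days` after the previous discharge (running maximum over earlier
#' discharges, so overlapping or contained stays never break a chain).
#' Provider changes do not break chains. Records are sorted by admission
#' date first; fully duplicated records are dropped with a warning.
#'
#' @param stays_of_patient Stay table (one patient) with `admit_date` and
#'   `discharge_date` columns.
#' @param gap_days Maximum allowed gap in days (default 1: admission on the
#'   same or next calendar day continues the episode).
#' @return List of data.tables, one per chain, in chronological order.
#' @export
chain_stays <- function(stays_of_patient, gap_days = 1L) {
  st <- data.table::as.data.table(stays_of_patient)
  if (length(unique(st$patient_id)) > 1L)
    stopf("chain_stays expects stays of a single patient")
  st <- assign_chains(st, gap_days)
  split(st, by = "chain_id", keep.by = TRUE)
}

# Adds a chain_id column (per patient); input may cover many patients.
assign_chains <- function(stays, gap_days = 1L) {
  if (gap_days < 0) stopf("gap_days must be >= 0")
  st <- data.table::copy(data.table::as.data.table(stays))
  ndup <- nrow(st) - data.table::uniqueN(st)
  if (ndup > 0L) {
    warnf("dropping %d fully duplicated stay record(s)", ndup)
    st <- unique(st)
  }
  if (any(st$discharge_date < st$admit_date))
    stopf("stay with discharge_date before admit_date")
  data.table::setorder(st, patient_id, admit_date, discharge_date)
  st[, `:=`(.cm = cummax(as.integer(discharge_date))), by = patient_id]
  st[, `:=`(.new = {
    prev <- data.table::shift(.cm)
    as.integer(is.na(prev) | as.integer(admit_date) > prev + gap_days)
  }), by = patient_id]
  st[, chain_id := cumsum(.new), by = patient_id]
  st[, c(".cm", ".new") := NULL]
  st[]
}

#' Select index episodes per patient and calendar year
#'
#' For every patient and calendar year, the first chain whose first
#' stroke-coded stay falls in that year becomes a candidate episode with
#' that stay's admission as the index date. Each candidate carries the
#' dominant stroke subtype of its chain, the acute-care segment end, flags
#' for a previous stroke inside the 365-day washout window (a stroke-coded
#' stay overlapping the 365 days before the index, outside the episode's own
#' chain) and beyond it (previous-stroke comorbidity), and the episode end.
#'
#' @param stays Stay table (any number of patients) with chain assignment
#'   from [assign_chains()]; columns without `chain_id` are chained here
#'   with `gap_days`.
#' @param gap_days Transfer gap rule, see [chain_stays()].
#' @param study_years Optional integer vector; candidate episodes are kept
#'   only for these cohort years (stays outside still contribute history for
#'   the washout and comorbidity flags).
#' @return data.table of candidate episodes: `patient_id`, `chain_id`,
#'   `cohort_year`, `index_date`, `acute_end_date`, `episode_end_date`,
#'   `dominant_dx`, `n_stays`, `recent_prior_stroke`, `prior_stroke`.
#' @export
select_index_episodes <- function(stays, gap_days = 1L, study_years = NULL) {
  st <- data.table::copy(data.table::as.data.table(stays))
  if (!"chain_id" %in% names(st)) st <- assign_chains(st, gap_days)
  if (nrow(st) == 0L) return(empty_episodes())
  st[, .stroke := is_stroke_code(main_dx)]
  strokes <- st[.stroke == TRUE]
  if (nrow(strokes) == 0L) return(empty_episodes())

  strokes[, .rk := match(substr(main_dx, 1L, 3L), stroke_prefixes)]
  chains <- strokes[, .(.idx = min(as.integer(admit_date)), .rk = min(.rk)),
                    by = .(patient_id, chain_id)]
  chains[, index_date := as_date(.idx)]
  chains[, dominant_dx := c("SAH", "ICH", "infarction", "ill_defined")[.rk]]
  chains[, cohort_year := year_of(index_date)]
  # first stroke chain starting in each (patient, year)
  data.table::setorder(chains, patient_id, .idx)
  cand <- unique(chains, by = c("patient_id", "cohort_year"))
  if (!is.null(study_years)) cand <- cand[cohort_year %in% study_years]
  if (nrow(cand) == 0L) return(empty_episodes())
  cand[, c(".idx", ".rk") := NULL]

  # episode extent and acute segment over the chain's stays from the index on
  ep_stays <- st[cand[, .(patient_id, chain_id, index_date)],
                 on = c("patient_id", "chain_id")][admit_date >= index_date]
  ep_stays[, `:=`(.ai = as.integer(admit_date),
                  .di = as.integer(discharge_date))]
  data.table::setorder(ep_stays, patient_id, chain_id, .ai, .di)
  ep_stays[, .nonac := cumsum(provider_type != "acute_hospital"),
           by = .(patient_id, chain_id)]
  seg <- ep_stays[, .(.ep_end = max(.di), n_stays = .N),
                  by = .(patient_id, chain_id)]
  ac <- ep_stays[.nonac == 0L, .(.ac_end = max(.di)),
                 by = .(patient_id, chain_id)]
  seg <- ac[seg, on = c("patient_id", "chain_id")]
  seg[, episode_end_date := as_date(.ep_end)]
  ep <- seg[cand, on = c("patient_id", "chain_id")]
  ep[, acute_end_date := data.table::fifelse(is.na(.ac_end), index_date,
                                             as_date(.ac_end))]
  ep[, c(".ep_end", ".ac_end") := NULL]

  # stroke history outside the episode's own chain
  hist <- strokes[ep[, .(patient_id, chain_id, index_date)],
                  on = "patient_id", allow.cartesian = TRUE]
  hist <- hist[chain_id != i.chain_id & admit_date < index_date]
  flags <- hist[, .(
    recent_prior_stroke = any(discharge_date >= index_date - 365L),
    prior_stroke = any(discharge_date < index_date - 365L)),
    by = .(patient_id, i.chain_id)]
  data.table::setnames(flags, "i.chain_id", "chain_id")
  ep <- flags[ep, on = c("patient_id", "chain_id")]
  ep[is.na(recent_prior_stroke), recent_prior_stroke := FALSE]
  ep[is.na(prior_stroke), prior_stroke := FALSE]

  data.table::setcolorder(ep, c("patient_id", "chain_id", "cohort_year",
                                "index_date", "acute_end_date",
                                "episode_end_date", "dominant_dx", "n_stays",
                                "recent_prior_stroke", "prior_stroke"))
  data.table::setorder(ep, patient_id, index_date)
  ep[]
}

empty_episodes <- function() {
  data.table::data.table(
    patient_id = character(), chain_id = integer(), cohort_year = integer(),
    index_date = as.Date(character()), acute_end_date = as.Date(character()),
    episode_end_date = as.Date(character()), dominant_dx = character(),
    n_stays = integer(), recent_prior_stroke = logical(),
    prior_stroke = logical())
}

#' End of the acute-care segment of an episode
#'
#' The acute segment is the maximal leading run of chained stays at an acute
#' hospital; its end is the (running-maximum) discharge date of the last such
#' stay. If the first stay of the episode is non-acute the acute segment is
#' empty and the index date is returned.
#'
#' @param episode_stays Stays of one episode, any order.
#' @param index_date The episode's index admission date.
#' @return The acute segment end date.
#' @export
split_acute_segment <- function(episode_stays, index_date) {
  st <- data.table::as.data.table(episode_stays)
  data.table::setorder(st, admit_date, discharge_date)
  lead_acute <- cumprod(st$provider_type == "acute_hospital") == 1
  if (!any(lead_acute)) return(as.Date(index_date))
  as_date(max(as.integer(st$discharge_date)[lead_acute]))
}

#' Apply the cohort inclusion and exclusion rules
#'
#' Candidate episodes are kept when the dominant subtype is cerebral
#' infarction, no stroke-coded stay overlaps the 365 days before the index
#' admission, the (optional) incomplete-identity flag is unset, and the
#' patient was not in long-term institutional care before the index. Rules
#' are applied in that fixed order and the first matching rule wins, so the
#' exclusion log is deterministic and its counts sum to the input size.
#'
#' @param episodes Candidate episodes from [select_index_episodes()].
#' @param patients Patient table with `pre_index_ltc` and optionally
#'   `incomplete_id`.
#' @return List with `included` (episodes joined with region/demographics),
#'   `excluded` (episodes with an `exclusion_reason`), and `log`
#'   (data.table of per-rule counts; attributes `n_input`, `n_included`).
#' @export
apply_cohort_filters <- function(episodes, patients) {
  ep <- data.table::as.data.table(episodes)
  pt <- data.table::as.data.table(patients)
  keep_cols <- intersect(c("patient_id", "pre_index_ltc", "incomplete_id"),
                         names(pt))
  ep <- pt[, keep_cols, with = FALSE][ep, on = "patient_id"]
  if (!"incomplete_id" %in% names(ep)) ep[, incomplete_id := FALSE]
  ep[is.na(incomplete_id), incomplete_id := FALSE]
  ep[is.na(pre_index_ltc), pre_index_ltc := FALSE]

  reason <- rep(NA_character_, nrow(ep))
  reason[is.na(reason) & ep$dominant_dx != "infarction"] <- "non_ischaemic"
  reason[is.na(reason) & ep$recent_prior_stroke] <- "recent_stroke"
  reason[is.na(reason) & ep$incomplete_id] <- "incomplete_id"
  reason[is.na(reason) & ep$pre_index_ltc] <- "long_term_care"
  ep[, exclusion_reason := reason]

  rules <- c("non_ischaemic", "recent_stroke", "incomplete_id",
             "long_term_care")
  log <- data.table::data.table(
    reason = rules,
    n = vapply(rules, function(r) sum(reason == r, na.rm = TRUE), integer(1)))
  included <- ep[is.na(exclusion_reason)][, c("exclusion_reason",
                                              "incomplete_id") := NULL]
  excluded <- ep[!is.na(exclusion_reason)]
  data.table::setattr(log, "n_input", nrow(ep))
  data.table::setattr(log, "n_included", nrow(included))
  list(included = included[], excluded = excluded[], log = log[])
}

#' Build filtered first institutional episodes from raw tables
#'
#' Driver combining [assign_chains()], [select_index_episodes()] and
#' [apply_cohort_filters()].
#'
#' @inheritParams select_index_episodes
#' @param patients Patient table.
#' @return List with `episodes` (included), `excluded`, `log`, and `stays`
#'   (the chained stay table).
#' @export
build_episodes <- function(stays, patients, gap_days = 1L,
                           study_years = NULL) {
  st <- assign_chains(stays, gap_days)
  cand <- select_index_episodes(st, gap_days, study_years)
  flt <- apply_cohort_filters(cand, patients)
  list(episodes = flt$included, excluded = flt$excluded, log = flt$log,
       stays = st)
}
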