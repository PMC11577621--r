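#' Generate a linked synthetic patient/stay discharge register
#'
#' Simulates a hospital discharge register with the structure the downstream
#' analysis assumes: per-year cohorts of stroke admissions across three
#' regions, multi-stay transfer chains forming a first institutional episode,
#' day-90 placement (home versus continued institutional care), two-piece
#' mortality (within 90 days, 91-365 days), later readmissions, and per-diem
#' cost structure via cost-group codes on acute stays.
#'
#' The outcome-generating process is calibrated cell-by-cell (region x year)
#' so that, in expectation, the measured indicators hit the configured
#' targets and any configured intervention effect equals the true
#' difference-in-difference effect on the indicator's natural scale:
#' probability targets are hit exactly in-sample expectation via a calibrated
#' logit shift on top of covariate effects, and length effects are injected
#' into the 90-day-survivor draw scaled by 1/P(alive at 90) (patients dying
#' within 90 days die in care, so their episode length is their survival time
#' and carries no intervention signal).
#'
#' @param config A [scenario_config()] object.
#' @return A list of class `stroke_register` with elements `patients`
#'   (one row per patient: id, birth date, sex, region, death date, 16
#'   comorbidity flags `cb01`..`cb16`, `pre_index_ltc`), `stays` (one row per
#'   admission interval: patient id, admit/discharge dates, provider id and
#'   type, specialty, main ICD-10 diagnosis, cost group), `truth` (the
#'   ground-truth intervention effects) and `config`.
#' @seealso [inject_noncollapsible_cases()], [write_register()]
#' @export
generate_register <- function(config) {
  cfg <- validate_scenario(config)
  set.seed(cfg$seed)
  years <- seq(cfg$years[1], cfg$years[2])
  n <- cfg$n_patients_per_year * length(years)
  truth <- scenario_ground_truth(cfg)
  if (n == 0L) {
    return(structure(list(patients = empty_patients(), stays = empty_stays(),
                          truth = truth, config = cfg),
                     class = "stroke_register"))
  }
  cm <- cfg$covariate_model
  shares <- cfg$region_shares[region_levels()]

  P <- data.table::data.table(
    patient_id = sprintf("P%07d", seq_len(n)),
    cohort_year = rep(years, each = cfg$n_patients_per_year)
  )
  P[, region := sample(region_levels(), .N, replace = TRUE,
                       prob = as.numeric(shares))]
  P[, index_date := as.Date(sprintf("%d-01-01", cohort_year)) +
        sample(0:364, .N, replace = TRUE)]
  P[, age := pmin(pmax(rnorm(.N, cm$age_mean, cm$age_sd), 30), 100)]
  P[, sex := ifelse(runif(.N) < cm$p_female, "female", "male")]
  comorb <- vapply(seq_len(16L),
                   function(j) runif(n) < cm$comorb_prev[j], logical(n))
  colnames(comorb) <- sprintf("cb%02d", seq_len(16L))
  for (j in colnames(comorb)) data.table::set(P, j = j, value = comorb[, j])
  P[, pre_index_ltc := runif(.N) < cfg$ltc_rate]
  P[, main_dx := paste0(sample(names(cfg$dx_probs), .N, replace = TRUE,
                               prob = as.numeric(cfg$dx_probs)),
                        sample(0:9, .N, replace = TRUE))]

  # linear predictors for covariate heterogeneity
  X <- cbind((P$age - cm$age_mean) / cm$age_sd, P$sex == "female", comorb * 1)
  eta_los <- as.numeric(X %*% cm$beta_los)
  eta_inst <- as.numeric(X %*% cm$beta_inst)
  eta_death <- as.numeric(X %*% cm$beta_death)
  P[, `:=`(eta_los = eta_los, eta_inst = eta_inst, eta_death = eta_death)]

  cells <- scenario_cell_params(cfg)
  m <- cells[P[, .(region, year = cohort_year)], on = c("region", "year"),
             which = TRUE]
  for (col in c("acute_mean", "episode_mean", "p_inst90", "p_dead90",
                "p_dead1y", "eff_acute", "eff_episode")) {
    data.table::set(P, j = col, value = cells[[col]][m])
  }

  # mortality: two-piece, calibrated per cell on the covariate log-odds
  P[, p90i := calibrate_logit_probs(eta_death, p_dead90[1]),
    by = .(region, cohort_year)]
  P[, p1yi := calibrate_logit_probs(eta_death, p_dead1y[1]),
    by = .(region, cohort_year)]
  P[, died_90 := runif(.N) < p90i]
  P[, p_late := pmin(1, pmax(0, (p1yi - p90i) / pmax(1e-12, 1 - p90i)))]
  P[, died_1y := died_90 | (runif(.N) < p_late)]
  u <- runif(n)
  off <- rep(NA_integer_, n)
  off[P$died_90] <- 1L + as.integer(floor(u[P$died_90] * 89))
  late <- P$died_1y & !P$died_90
  off[late] <- 91L + as.integer(floor(u[late] * 274))
  P[, death_offset := off]

  # day-90 placement among survivors; configured probability is the
  # unconditional share, converted to a conditional target per cell
  P[, inst_target := pmin(1, p_inst90 / pmax(1e-12, 1 - p_dead90))]
  P[, pinsti := 0]
  P[died_90 == FALSE, pinsti := calibrate_logit_probs(eta_inst, inst_target[1]),
    by = .(region, cohort_year)]
  P[, inst_90 := died_90 == FALSE & runif(.N) < pinsti]

  # lengths: gamma draws around cell means with mean-one covariate multiplier
  P[, m_los := exp(eta_los)]
  P[died_90 == FALSE, m_los := m_los / mean(m_los), by = .(region, cohort_year)]
  alive <- !P$died_90
  P[, mu_ep := pmax(1, episode_mean + eff_episode / pmax(0.05, 1 - p_dead90))]
  P[, mu_ac := pmax(0.5, acute_mean + eff_acute / pmax(0.05, 1 - p_dead90))]
  # home-discharged survivors are capped at 90 days; compensate the draw mean
  # so the capped mean still equals the target
  home <- alive & !P$inst_90
  mu_i <- P$mu_ep * P$m_los
  mu_i[home] <- gamma2_capped_mean(mu_i[home], 90)
  E <- pmax(1L, as.integer(round(rgamma(n, shape = 2, scale = mu_i / 2))))
  A <- pmax(1L, as.integer(round(rgamma(n, shape = 2,
                                        scale = P$mu_ac * P$m_los / 2))))
  # survivors discharged home by day 90; institutionalized survivors either
  # remain in the episode past day 90 or move to a later long-term placement
  E[home] <- pmin(E[home], 90L)
  force_long <- alive & P$inst_90 & E > 88L
  E[force_long] <- pmax(E[force_long], 91L)
  # patients dying within 90 days die in care
  E[!alive] <- P$death_offset[!alive]
  # late deaths truncate any episode still running
  trunc_late <- late & E > P$death_offset
  E[trunc_late] <- P$death_offset[trunc_late]
  A <- pmin(A, E)
  P[, `:=`(episode_days = E, acute_days = A)]

  stays <- assemble_stays(P, cfg)

  patients <- P[, .(patient_id,
                    birth_date = index_date - as.integer(round(age * 365.25)),
                    sex, region,
                    death_date = data.table::fifelse(
                      is.na(death_offset), as.Date(NA),
                      index_date + death_offset))]
  patients <- cbind(patients, P[, c(sprintf("cb%02d", 1:16)), with = FALSE],
                    P[, .(pre_index_ltc)])

  structure(list(patients = patients, stays = stays, truth = truth,
                 config = cfg),
            class = "stroke_register")
}

empty_patients <- function() {
  pt <- data.table::data.table(
    patient_id = character(), birth_date = as.Date(character()),
    sex = character(), region = character(),
    death_date = as.Date(character()))
  for (j in sprintf("cb%02d", 1:16)) pt[[j]] <- logical()
  pt$pre_index_ltc <- logical()
  pt
}

empty_stays <- function() {
  data.table::data.table(
    patient_id = character(), admit_date = as.Date(character()),
    discharge_date = as.Date(character()), provider_id = character(),
    provider_type = character(), specialty = character(),
    main_dx = character(), cost_group = character())
}

# Build the stay table realizing each patient's episode, placement, and
# later admissions. All draws are vectorized; stay segments are assembled as
# blocks and bound together.
assemble_stays <- function(P, cfg) {
  n <- nrow(P)
  tm <- cfg$transfer_model
  A <- P$acute_days
  E <- P$episode_days
  idx <- P$index_date
  u_split_a <- runif(n); u_cut_a <- runif(n); u_gap_a <- runif(n)
  u_split_n <- runif(n); u_cut_n <- runif(n); u_gap_n <- runif(n)
  prov_a <- sprintf("H%03d", sample(40L, n, replace = TRUE))
  prov_a2 <- sprintf("H%03d", sample(40L, n, replace = TRUE))
  prov_n <- sprintf("HC%03d", sample(80L, n, replace = TRUE))
  prov_n2 <- sprintf("HC%03d", sample(80L, n, replace = TRUE))
  cg <- function(k) sample(names(cfg$cost_model$cost_groups), k, replace = TRUE)
  cg_a1 <- cg(n); cg_a2 <- cg(n); cg_re <- cg(n)

  split_a <- u_split_a < tm$p_split_acute & A >= 4L
  cut_a <- pmin(pmax(1L, as.integer(1 + floor(u_cut_a * (A - 2L)))), A - 2L)
  gap_a <- as.integer(u_gap_a < tm$p_gap1)
  gap_a[cut_a + gap_a >= A] <- 0L

  a1_end <- data.table::fifelse(split_a, cut_a, A)
  s_a1 <- data.table::data.table(
    patient_id = P$patient_id, admit_date = idx,
    discharge_date = idx + a1_end, provider_id = prov_a,
    provider_type = "acute_hospital", specialty = "15",
    main_dx = P$main_dx, cost_group = cg_a1)

  s_a2 <- data.table::data.table(
    patient_id = P$patient_id[split_a],
    admit_date = idx[split_a] + cut_a[split_a] + gap_a[split_a],
    discharge_date = idx[split_a] + A[split_a], provider_id = prov_a2[split_a],
    provider_type = "acute_hospital", specialty = "15",
    main_dx = P$main_dx[split_a], cost_group = cg_a2[split_a])

  has_n <- E > A
  len_n <- E - A
  split_n <- u_split_n < tm$p_split_nonacute & has_n & len_n >= 4L
  cut_n <- A + pmin(pmax(1L, as.integer(1 + floor(u_cut_n * (len_n - 2L)))),
                    len_n - 2L)
  gap_n <- as.integer(u_gap_n < tm$p_gap1)
  gap_n[cut_n + gap_n >= E] <- 0L
  n1_end <- data.table::fifelse(split_n, cut_n, E)

  s_n1 <- data.table::data.table(
    patient_id = P$patient_id[has_n], admit_date = idx[has_n] + A[has_n],
    discharge_date = idx[has_n] + n1_end[has_n], provider_id = prov_n[has_n],
    provider_type = "health_centre", specialty = "98",
    main_dx = P$main_dx[has_n], cost_group = NA_character_)

  s_n2 <- data.table::data.table(
    patient_id = P$patient_id[split_n],
    admit_date = idx[split_n] + cut_n[split_n] + gap_n[split_n],
    discharge_date = idx[split_n] + E[split_n], provider_id = prov_n2[split_n],
    provider_type = "health_centre", specialty = "98",
    main_dx = P$main_dx[split_n], cost_group = NA_character_)

  # later long-term placement covering day 90 for institutionalized
  # survivors whose episode ended by day 88 (gap >= 2 so the placement does
  # not chain into the first episode)
  pl <- !P$died_90 & P$inst_90 & E <= 88L
  gap_p <- pmax(2L, pmin(2L + as.integer(floor(runif(n) * 6)), 90L - E))
  start_p <- E + gap_p
  dur_p <- (91L - start_p) + as.integer(rgeom(n, 1 / 90))
  end_off <- start_p + dur_p
  death_off <- P$death_offset
  cap <- !is.na(death_off) & end_off > death_off
  end_off[cap] <- death_off[cap]
  s_pl <- data.table::data.table(
    patient_id = P$patient_id[pl], admit_date = idx[pl] + start_p[pl],
    discharge_date = idx[pl] + end_off[pl],
    provider_id = sprintf("NH%03d", sample(30L, sum(pl), replace = TRUE)),
    provider_type = "nursing_home", specialty = "98",
    main_dx = "I69", cost_group = NA_character_)

  # unrelated acute readmission later in the index year
  re_ok <- runif(n) < cfg$readmit_rate & E < 300L &
    (is.na(death_off) | death_off > E + 30L)
  re_last <- pmin(320L, data.table::fifelse(is.na(death_off), 320L,
                                            death_off - 5L))
  re_start <- E + 3L + as.integer(floor(runif(n) * pmax(1L, re_last - E - 3L)))
  re_ok <- re_ok & re_start > E + 2L & re_start < re_last
  re_dur <- 3L + as.integer(floor(runif(n) * 12))
  re_end <- re_start + re_dur
  cap <- !is.na(death_off) & re_end > death_off
  re_end[cap] <- death_off[cap]
  s_re <- data.table::data.table(
    patient_id = P$patient_id[re_ok], admit_date = idx[re_ok] + re_start[re_ok],
    discharge_date = idx[re_ok] + re_end[re_ok],
    provider_id = sprintf("H%03d", sample(40L, sum(re_ok), replace = TRUE)),
    provider_type = "acute_hospital", specialty = "10",
    main_dx = "J18", cost_group = cg_re[re_ok])

  # occasional psychiatric inpatient stay
  ps_ok <- runif(n) < cfg$psych_rate & E < 250L &
    (is.na(death_off) | death_off > E + 80L)
  ps_start <- E + 10L + as.integer(floor(runif(n) * 60))
  ps_dur <- 10L + as.integer(floor(runif(n) * 50))
  ps_end <- ps_start + ps_dur
  cap <- !is.na(death_off) & ps_end > death_off
  ps_end[cap] <- death_off[cap]
  s_ps <- data.table::data.table(
    patient_id = P$patient_id[ps_ok], admit_date = idx[ps_ok] + ps_start[ps_ok],
    discharge_date = idx[ps_ok] + ps_end[ps_ok],
    provider_id = sprintf("PS%02d", sample(10L, sum(ps_ok), replace = TRUE)),
    provider_type = "psychiatric", specialty = "70",
    main_dx = "F03", cost_group = NA_character_)

  stays <- data.table::rbindlist(list(s_a1, s_a2, s_n1, s_n2, s_pl, s_re, s_ps))
  data.table::setorder(stays, patient_id, admit_date, discharge_date)
  stays[]
}

#' Plant edge-case records into a generated register
#'
#' Adds, at configurable rates, the situations the cohort rules must handle:
#' (a) a prior stroke admission 100 days before the index admission (inside
#' the 365-day washout, so the episode must be excluded), (b) a prior stroke
#' admission 400 days before the index (outside the washout; kept, with the
#' previous stroke as a comorbidity), (c) a pre-index long-term-care flag
#' (excluded), and (d) an intracerebral-haemorrhage-coded stay inside an
#' infarction episode (the subtype hierarchy resolves the episode to ICH and
#' it leaves the ischaemic cohort).
#'
#' @param stays,patients Tables from [generate_register()].
#' @param rates Named list with any of `recent_prior`, `old_prior`, `pre_ltc`,
#'   `mixed_dx`, each a probability in `[0,1]` (default 0).
#' @param seed Optional seed for the planting draws.
#' @return List with modified `stays`, `patients`, and `counts` (named integer
#'   vector of planted cases per type, for test assertions).
#' @export
inject_noncollapsible_cases <- function(stays, patients,
                                        rates = list(), seed = NULL) {
  defaults <- list(recent_prior = 0, old_prior = 0, pre_ltc = 0, mixed_dx = 0)
  unknown <- setdiff(names(rates), names(defaults))
  if (length(unknown))
    stopf("invalid rate name: %s", paste(unknown, collapse = ", "))
  rates <- utils::modifyList(defaults, rates)
  for (nm in names(rates)) {
    if (rates[[nm]] < 0 || rates[[nm]] > 1)
      stopf("invalid field '%s': rate must be in [0,1]", nm)
  }
  if (!is.null(seed)) set.seed(seed)
  stays <- data.table::copy(data.table::as.data.table(stays))
  patients <- data.table::copy(data.table::as.data.table(patients))
  counts <- c(recent_prior = 0L, old_prior = 0L, pre_ltc = 0L, mixed_dx = 0L)

  stroke <- stays[is_stroke_code(main_dx)]
  if (nrow(stroke) == 0L) {
    return(list(stays = stays, patients = patients, counts = counts))
  }
  index <- stroke[, .(index_date = min(admit_date),
                      index_dx = main_dx[which.min(admit_date)]),
                  by = patient_id]

  plant_prior <- function(idx_rows, offset, span, prov) {
    data.table::data.table(
      patient_id = idx_rows$patient_id,
      admit_date = idx_rows$index_date - offset,
      discharge_date = idx_rows$index_date - offset + span,
      provider_id = prov, provider_type = "acute_hospital",
      specialty = "15", main_dx = "I639", cost_group = "C03")
  }

  new_stays <- list()
  if (rates$recent_prior > 0) {
    pick <- index[runif(.N) < rates$recent_prior]
    counts["recent_prior"] <- nrow(pick)
    if (nrow(pick))
      new_stays <- c(new_stays, list(plant_prior(pick, 100L, 5L, "H900")))
  }
  if (rates$old_prior > 0) {
    pick <- index[runif(.N) < rates$old_prior]
    counts["old_prior"] <- nrow(pick)
    if (nrow(pick))
      new_stays <- c(new_stays, list(plant_prior(pick, 400L, 7L, "H902")))
  }
  if (rates$pre_ltc > 0) {
    pick <- index[runif(.N) < rates$pre_ltc, patient_id]
    counts["pre_ltc"] <- length(pick)
    patients[patient_id %in% pick, pre_index_ltc := TRUE]
  }
  if (rates$mixed_dx > 0) {
    elig <- index[startsWith(index_dx, "I63")]
    pick <- elig[runif(.N) < rates$mixed_dx]
    counts["mixed_dx"] <- nrow(pick)
    if (nrow(pick)) {
      new_stays <- c(new_stays, list(data.table::data.table(
        patient_id = pick$patient_id, admit_date = pick$index_date,
        discharge_date = pick$index_date, provider_id = "H901",
        provider_type = "acute_hospital", specialty = "15",
        main_dx = "I611", cost_group = "C03")))
    }
  }
  if (length(new_stays)) {
    stays <- data.table::rbindlist(c(list(stays), new_stays), use.names = TRUE)
    data.table::setorder(stays, patient_id, admit_date, discharge_date)
  }
  list(stays = stays, patients = patients, counts = counts)
}

#' Write / read a register as delimited files
#'
#' Patient and stay tables are written as comma-separated files with ISO-8601
#' dates and a header row; the ground truth as a key-value text file.
#'
#' @param reg A `stroke_register`.
#' @param dir Output directory (created if missing).
#' @return `write_register` returns `dir` invisibly; `read_register` returns
#'   a list with `patients`, `stays`, and `truth` (NULL if absent).
#' @export
write_register <- function(reg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(reg$patients, file.path(dir, "patients.csv"))
  data.table::fwrite(reg$stays, file.path(dir, "stays.csv"))
  tr <- reg$truth
  lines <- if (nrow(tr)) {
    sprintf("%s.%s.%s.%d = %.10g", tr$intervention, tr$outcome,
            tr$regions, tr$year, tr$effect)
  } else character()
  writeLines(lines, file.path(dir, "ground_truth.txt"))
  invisible(dir)
}

#' @rdname write_register
#' @export
read_register <- function(dir) {
  patients <- data.table::fread(file.path(dir, "patients.csv"))
  stays <- data.table::fread(file.path(dir, "stays.csv"))
  for (col in c("admit_date", "discharge_date"))
    stays[[col]] <- as.Date(stays[[col]])
  for (col in c("birth_date", "death_date"))
    patients[[col]] <- as.Date(patients[[col]])
  tfile <- file.path(dir, "ground_truth.txt")
  truth <- NULL
  if (file.exists(tfile)) {
    ln <- readLines(tfile)
    ln <- ln[nzchar(ln)]
    if (length(ln)) {
      parts <- strsplit(sub(" = .*$", "", ln), ".", fixed = TRUE)
      truth <- data.table::data.table(
        intervention = vapply(parts, `[`, "", 1L),
        outcome = vapply(parts, `[`, "", 2L),
        regions = vapply(parts, `[`, "", 3L),
        year = as.integer(vapply(parts, `[`, "", 4L)),
        effect = as.numeric(sub("^.* = ", "", ln)))
    }
  }
  list(patients = patients, stays = stays, truth = truth)
}
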