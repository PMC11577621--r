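# brute-force oracle: partition stays by transitive closure of the
# "admission within gap_days of an earlier discharge or overlapping" relation
bf_chain_partition <- function(admit, discharge, gap) {
  n <- length(admit)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      lo <- max(admit[i], admit[j])
      hi <- min(discharge[i], discharge[j])
      linked <- (lo <= hi) ||
        (admit[j] > discharge[i] && admit[j] - discharge[i] <= gap) ||
        (admit[i] > discharge[j] && admit[i] - discharge[j] <= gap)
      adj[i, j] <- linked
    }
  }
  reach <- adj
  for (k in seq_len(n)) reach <- reach | (reach %*% (reach * 1) > 0)
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  comp
}

rand_stays <- function(n, pid = "P1") {
  a <- sample(0:60, n, replace = TRUE)
  d <- a + sample(0:10, n, replace = TRUE)
  unique(data.table::data.table(
    patient_id = pid, admit_date = as.Date("2005-01-01") + a,
    discharge_date = as.Date("2005-01-01") + d,
    provider_id = sample(c("H1", "H2", "HC1"), n, TRUE),
    provider_type = sample(c("acute_hospital", "health_centre",
                             "nursing_home"), n, TRUE),
    specialty = "15", main_dx = "I639",
    cost_group = "C01"))
}

test_that("transfer chains merge same- and next-day admissions across providers", {
  st <- data.table::data.table(
    patient_id = "P1",
    admit_date = as.Date(c("2005-01-01", "2005-01-06")),
    discharge_date = as.Date(c("2005-01-06", "2005-01-21")),
    provider_id = c("H1", "HC2"),
    provider_type = c("acute_hospital", "health_centre"),
    specialty = "15", main_dx = "I639", cost_group = "C01")
  expect_length(chain_stays(st, gap_days = 1), 1L)

  st$admit_date[2] <- as.Date("2005-01-09") # 3-day gap
  expect_length(chain_stays(st, gap_days = 1), 2L)
  expect_length(chain_stays(st, gap_days = 3), 1L)
  expect_error(chain_stays(st, gap_days = -1), "gap_days")
})

test_that("chaining matches the brute-force transitive-closure oracle", {
  set.seed(42)
  for (rep in 1:30) {
    st <- rand_stays(sample(2:12, 1))
    gap <- sample(0:2, 1)
    got <- assign_chains(st, gap)
    # same partition: compare by grouping structure on the original rows
    got[, key := paste(admit_date, discharge_date, provider_id)]
    st2 <- data.table::copy(st)
    st2[, comp := bf_chain_partition(as.integer(admit_date),
                                     as.integer(discharge_date), gap)]
    st2[, key := paste(admit_date, discharge_date, provider_id)]
    merged <- merge(unique(got[, .(key, chain_id)]),
                    unique(st2[, .(key, comp)]), by = "key")
    tab <- table(merged$chain_id, merged$comp)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("chain assignment is invariant to input stay order", {
  set.seed(11)
  st <- rand_stays(10)
  a <- assign_chains(st, 1L)
  b <- assign_chains(st[sample(.N)], 1L)
  data.table::setorder(a, admit_date, discharge_date, provider_id)
  data.table::setorder(b, admit_date, discharge_date, provider_id)
  expect_identical(a$chain_id, b$chain_id)
})

test_that("fully duplicated stays are dropped with a warning", {
  st <- rand_stays(4)
  expect_warning(out <- assign_chains(rbind(st, st[2]), 1L), "duplicated")
  expect_equal(nrow(out), 4L)
})

test_that("dominant diagnosis follows the severity hierarchy on 3-character prefixes", {
  expect_equal(resolve_dominant_dx(c("I630", "I611")), "ICH")
  expect_equal(resolve_dominant_dx("I63"), "infarction")
  expect_equal(resolve_dominant_dx(c("I60", "I61", "I63", "I64")), "SAH")
  expect_equal(resolve_dominant_dx(c("I64", "I639")), "infarction")
  expect_equal(resolve_dominant_dx(c("J18", "I649")), "ill_defined")
  expect_error(resolve_dominant_dx(c("J18", "A01")), "no stroke code")
})

test_that("index selection keeps the first stroke chain per patient-year and flags history", {
  mk <- function(...) {
    rows <- list(...)
    data.table::rbindlist(lapply(rows, function(r) {
      data.table::data.table(patient_id = "P1",
                             admit_date = as.Date(r[1]),
                             discharge_date = as.Date(r[2]),
                             provider_id = "H1",
                             provider_type = "acute_hospital",
                             specialty = "15", main_dx = r[3],
                             cost_group = "C01")
    }))
  }
  # one chain -> one episode in its cohort year
  ep <- select_index_episodes(mk(c("2005-03-01", "2005-03-10", "I630")))
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$cohort_year, 2005L)
  expect_equal(ep$index_date, as.Date("2005-03-01"))

  # 214-day gap: second admission is a candidate of its year but carries the
  # recent-prior flag, so the cohort filters remove it
  st <- mk(c("2005-05-20", "2005-06-01", "I630"),
           c("2006-01-01", "2006-01-15", "I630"))
  ep <- select_index_episodes(st)
  expect_equal(nrow(ep), 2L)
  expect_true(ep[cohort_year == 2006, recent_prior_stroke])
  flt <- apply_cohort_filters(ep, data.table::data.table(
    patient_id = "P1", pre_index_ltc = FALSE))
  expect_equal(flt$included$cohort_year, 2005L)
  expect_equal(flt$log[reason == "recent_stroke", n], 1L)

  # 579-day gap: both kept, the later one carries the previous stroke as a
  # comorbidity flag
  st <- mk(c("2005-05-20", "2005-06-01", "I630"),
           c("2007-01-01", "2007-01-15", "I630"))
  ep <- select_index_episodes(st)
  flt <- apply_cohort_filters(ep, data.table::data.table(
    patient_id = "P1", pre_index_ltc = FALSE))
  expect_equal(sort(flt$included$cohort_year), c(2005L, 2007L))
  expect_identical(flt$included[order(cohort_year), prior_stroke],
                   c(FALSE, TRUE))

  # two stroke chains in the same year: only the first is a candidate
  st <- mk(c("2005-02-01", "2005-02-10", "I630"),
           c("2005-11-01", "2005-11-05", "I630"))
  ep <- select_index_episodes(st)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$index_date, as.Date("2005-02-01"))
})

test_that("acute segment end matches a linear-scan oracle", {
  # hand cases
  st <- fixture_stays()
  expect_equal(split_acute_segment(st[patient_id == "F02"],
                                   as.Date("2005-04-01")),
               as.Date("2005-04-08"))
  expect_equal(split_acute_segment(st[patient_id == "F15"],
                                   as.Date("2005-05-20")),
               as.Date("2005-06-10"))
  # leading non-acute stay: acute end equals the index date
  nonac <- data.table::data.table(
    patient_id = "P1", admit_date = as.Date("2005-01-01"),
    discharge_date = as.Date("2005-01-20"), provider_id = "HC1",
    provider_type = "health_centre", specialty = "98", main_dx = "I630",
    cost_group = NA_character_)
  expect_equal(split_acute_segment(nonac, as.Date("2005-01-01")),
               as.Date("2005-01-01"))
  # random chains vs scan oracle
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    a <- cumsum(c(0, sample(0:5, n - 1, TRUE)))
    d <- a + sample(1:5, n, TRUE)
    types <- sample(c("acute_hospital", "health_centre"), n, TRUE)
    st <- data.table::data.table(
      patient_id = "P1", admit_date = as.Date("2005-01-01") + a,
      discharge_date = as.Date("2005-01-01") + d, provider_id = "H1",
      provider_type = types, specialty = "15", main_dx = "I630",
      cost_group = "C01")
    # oracle: walk stays in admission order until the first non-acute one
    end <- as.Date("2005-01-01")
    for (i in seq_len(n)) {
      if (types[i] != "acute_hospital") break
      end <- max(end, st$discharge_date[i])
    }
    expect_equal(split_acute_segment(st, as.Date("2005-01-01")), end)
  }
})

test_that("exclusion log counts sum to the number of candidate episodes", {
  cfg <- test_scenario(n_per_year = 400, years = c(2001, 2002), seed = 31,
                       ltc_rate = 0.05)
  reg <- generate_register(cfg)
  be <- build_episodes(reg$stays, reg$patients, 1L, 2001:2002)
  expect_equal(attr(be$log, "n_input"),
               nrow(be$episodes) + sum(be$log$n))
  expect_equal(attr(be$log, "n_included"), nrow(be$episodes))
  # every included episode is an incident ischaemic stroke
  expect_true(all(be$episodes$dominant_dx == "infarction"))
  expect_false(any(be$episodes$recent_prior_stroke))
})

test_that("episode construction matches a brute-force reimplementation on a small register", {
  cfg <- test_scenario(n_per_year = 120, years = c(2001, 2002), seed = 77,
                       ltc_rate = 0.05)
  reg <- generate_register(cfg)
  inj <- inject_noncollapsible_cases(reg$stays, reg$patients,
                                     list(recent_prior = 0.1,
                                          old_prior = 0.1,
                                          mixed_dx = 0.1), seed = 3)
  be <- build_episodes(inj$stays, inj$patients, 1L, 2001:2002)

  # brute-force: per patient, chain by scanning sorted stays, pick first
  # stroke chain per year, apply the filter rules literally
  strokeish <- function(dx) substr(dx, 1, 3) %in% c("I60", "I61", "I63", "I64")
  got <- be$episodes[order(patient_id, index_date),
                     .(patient_id, cohort_year, index_date,
                       episode_end_date, dominant_dx)]
  exp_rows <- list()
  for (pid in unique(inj$stays$patient_id)) {
    st <- inj$stays[patient_id == pid][order(admit_date, discharge_date)]
    pt <- inj$patients[patient_id == pid]
    cid <- 1L; ends <- as.integer(st$discharge_date[1])
    chains <- list(1L)
    if (nrow(st) > 1) {
      for (i in 2:nrow(st)) {
        if (as.integer(st$admit_date[i]) > max(ends) + 1L) {
          cid <- cid + 1L; chains[[cid]] <- i
          ends <- as.integer(st$discharge_date[i])
        } else {
          chains[[cid]] <- c(chains[[cid]], i)
          ends <- c(ends, as.integer(st$discharge_date[i]))
        }
      }
    }
    for (yr in 2001:2002) {
      cand <- NULL
      for (ch in chains) {
        s <- st[ch][strokeish(main_dx)]
        if (nrow(s) == 0) next
        idx <- min(s$admit_date)
        if (format(idx, "%Y") == as.character(yr)) { cand <- ch; break }
      }
      if (is.null(cand)) next
      s <- st[cand]
      idx <- min(s[strokeish(main_dx), admit_date])
      pre <- c("SAH", "ICH", "infarction", "ill_defined")
      dom <- pre[min(match(substr(s[strokeish(main_dx), main_dx], 1, 3),
                           c("I60", "I61", "I63", "I64")))]
      others <- st[-cand][strokeish(main_dx)]
      recent <- nrow(others[admit_date < idx &
                              discharge_date >= idx - 365]) > 0
      if (dom != "infarction" || recent || pt$pre_index_ltc) next
      exp_rows[[length(exp_rows) + 1L]] <- data.table::data.table(
        patient_id = pid, cohort_year = yr, index_date = idx,
        episode_end_date = max(s[admit_date >= idx, discharge_date]),
        dominant_dx = dom)
    }
  }
  expected <- data.table::rbindlist(exp_rows)[order(patient_id, index_date)]
  expect_equal(as.data.frame(got), as.data.frame(expected))
})
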