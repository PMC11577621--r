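test_that("episode lengths follow the floor-1 convention and truncate at death", {
  d0 <- as.Date("2005-01-01")
  len <- compute_lengths(d0, d0 + 7, d0 + 30)
  expect_equal(len$acute_los, 7L)
  expect_equal(len$episode_los, 30L)
  # same-day discharge counts as one day
  len <- compute_lengths(d0, d0, d0)
  expect_equal(unlist(len), c(acute_los = 1L, episode_los = 1L))
  # death on day 20 of a 30-day episode truncates (oracle: min of the
  # unmodified length and the survival time)
  len <- compute_lengths(d0, d0 + 7, d0 + 30, death_date = d0 + 20)
  expect_equal(len$episode_los, min(30L, 20L))
  expect_equal(len$acute_los, 7L)
})

test_that("mortality flags use the 90- and 365-day horizons and reject bad dates", {
  d0 <- as.Date("2005-01-01")
  mf <- mortality_flags(rep(d0, 3), c(d0 + 89, d0 + 200, as.Date(NA)))
  expect_equal(mf$died_90, c(TRUE, FALSE, FALSE))
  expect_equal(mf$died_1y, c(TRUE, TRUE, FALSE))
  expect_error(mortality_flags(d0, d0 - 1), "death_date before index")
})

test_that("day-90 placement is point-in-time occupancy, mutually exclusive, and null for the dead", {
  d0 <- as.Date("2005-01-01")
  stay <- function(a, d, type = "health_centre") {
    data.table::data.table(patient_id = "P1", admit_date = d0 + a,
                           discharge_date = d0 + d, provider_id = "X",
                           provider_type = type, specialty = "98",
                           main_dx = "I630", cost_group = NA_character_)
  }
  ep <- list(index_date = d0, episode_end_date = d0 + 25)
  expect_equal(placement_at_90(ep, stay(0, 25), NA),
               c(home_90 = TRUE, institutionalized_90 = FALSE))
  ep2 <- list(index_date = d0, episode_end_date = d0 + 120)
  expect_equal(placement_at_90(ep2, stay(0, 120), NA),
               c(home_90 = FALSE, institutionalized_90 = TRUE))
  expect_equal(placement_at_90(ep2, stay(0, 120), death_date = d0 + 40),
               c(home_90 = FALSE, institutionalized_90 = FALSE))
  # ever-discharged variant ignores a later re-institutionalization
  ep3 <- list(index_date = d0, episode_end_date = d0 + 25)
  st3 <- rbind(stay(0, 25), stay(80, 200, "nursing_home"))
  expect_equal(placement_at_90(ep3, st3, NA),
               c(home_90 = FALSE, institutionalized_90 = TRUE))
  expect_equal(placement_at_90(ep3, st3, NA, rule = "ever_discharged"),
               c(home_90 = TRUE, institutionalized_90 = TRUE))
})

test_that("1-year inpatient days merge overlaps, clip the window, and match a day-grid oracle", {
  d0 <- as.Date("2005-01-01")
  stay <- function(a, d) {
    data.table::data.table(patient_id = "P1", admit_date = d0 + a,
                           discharge_date = d0 + d, provider_id = "X",
                           provider_type = "health_centre", specialty = "98",
                           main_dx = "I630", cost_group = NA_character_)
  }
  expect_equal(inpatient_days_1y(stay(0, 30), d0), 30L)
  expect_equal(inpatient_days_1y(rbind(stay(0, 30), stay(20, 40)), d0), 40L)
  expect_equal(inpatient_days_1y(stay(300, 500), d0), 65L)
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(1:6, 1)
    a <- sample(-20:380, n, replace = TRUE)
    d <- a + sample(0:120, n, replace = TRUE)
    st <- data.table::rbindlist(lapply(seq_len(n),
                                       function(i) stay(a[i], d[i])))
    death <- if (runif(1) < 0.3) d0 + sample(5:400, 1) else NA
    got <- inpatient_days_1y(st, d0, death)
    # oracle: walk each calendar day of the year and test membership
    dd <- if (is.na(death)) d else pmin(d, as.integer(death - d0))
    keep <- dd >= a            # stays entirely after death are void
    dd <- pmax(dd, a + 1)      # same-day stays occupy one day
    days <- 0L
    for (day in 0:364)
      days <- days + any(keep & a <= day & dd > day)
    expect_equal(got, min(365L, days))
  }
})

test_that("stay costing multiplies days in window by the per-diem rate with fallbacks", {
  ct <- fixture_cost_table()
  d0 <- as.Date("2005-02-01")
  stay <- function(a, d, type, cg = NA, spec = "98") {
    data.table::data.table(patient_id = "P1", admit_date = d0 + a,
                           discharge_date = d0 + d, provider_id = "X",
                           provider_type = type, specialty = spec,
                           main_dx = "I630", cost_group = cg)
  }
  expect_equal(cost_stays(stay(0, 10, "acute_hospital", "C01"), ct,
                          d0, d0 + 365), 5000)
  two <- rbind(stay(0, 7, "acute_hospital", "C01"),
               stay(7, 27, "health_centre"))
  expect_equal(cost_stays(two, ct, d0, d0 + 365), 7 * 500 + 20 * 200)
  # unknown cost group falls back to the all-acute annual median
  expect_equal(cost_stays(stay(0, 4, "acute_hospital", "ZZZ"), ct,
                          d0, d0 + 365), 4 * 400)
  # unknown provider type errors by name
  expect_error(cost_stays(stay(0, 4, "spa_resort"), ct, d0, d0 + 365),
               "spa_resort")
  # randomized stay sets match a day-by-day accumulation oracle
  set.seed(8)
  for (rep in 1:15) {
    n <- sample(1:5, 1)
    sts <- data.table::rbindlist(lapply(seq_len(n), function(i) {
      a <- sample(0:80, 1)
      stay(a, a + sample(0:30, 1),
           sample(c("acute_hospital", "health_centre", "nursing_home",
                    "psychiatric"), 1),
           cg = sample(c("C01", "C02", NA), 1))
    }))
    w0 <- d0 + sample(0:20, 1); w1 <- w0 + sample(10:100, 1)
    got <- cost_stays(sts, ct, w0, w1)
    oracle <- 0
    for (i in seq_len(nrow(sts))) {
      r <- sts[i]
      rate <- if (r$provider_type == "acute_hospital") {
        if (!is.na(r$cost_group) && r$cost_group %in% c("C01", "C02")) {
          c(C01 = 500, C02 = 300)[[r$cost_group]]
        } else 400
      } else if (r$provider_type == "psychiatric") 250
      else c(health_centre = 200, nursing_home = 150)[[r$provider_type]]
      dend <- max(r$discharge_date, r$admit_date + 1)
      for (day in as.integer(w0):(as.integer(w1) - 1L)) {
        if (as.integer(r$admit_date) <= day && as.integer(dend) > day)
          oracle <- oracle + rate
      }
    }
    expect_equal(got, oracle)
  }
})

test_that("median per-diem rates use the median of admission-level costs with annual fallback", {
  adm <- data.table::data.table(
    cost_group = c("A", "A", "A", "B", "B"),
    year = 2005L,
    cost = c(4000, 5000, 6000, 4000, 6000),
    days = c(10, 10, 10, 10, 10))
  ct <- median_cost_per_day(adm, provider_rates = c(health_centre = 200,
                                                    nursing_home = 150,
                                                    other_longterm = 150))
  expect_equal(ct$acute[cost_group == "A", rate], 500)  # odd-count median
  expect_equal(ct$acute[cost_group == "B", rate], 500)  # mean of middle two
  # a group with no data in the year falls back to the all-acute median
  d0 <- as.Date("2005-03-01")
  st <- data.table::data.table(patient_id = "P1", admit_date = d0,
                               discharge_date = d0 + 2, provider_id = "X",
                               provider_type = "acute_hospital",
                               specialty = "15", main_dx = "I630",
                               cost_group = "C")
  expect_equal(cost_stays(st, ct, d0, d0 + 10),
               2 * median(adm$cost / adm$days))
  expect_error(median_cost_per_day(adm[0],
                                   provider_rates = c(health_centre = 200,
                                                      nursing_home = 150,
                                                      other_longterm = 150)),
               "no admission")
})

test_that("episode cost never exceeds the 1-year cost for episodes within a year", {
  out <- run_small_pipeline(test_scenario(n_per_year = 300, seed = 17))
  ind <- out$ind
  sub <- ind[episode_los <= 365]
  expect_true(all(sub$episode_cost <= sub$cost_1y + 1e-9))
  expect_true(all(ind$acute_los <= ind$episode_los))
  expect_true(all(ind$inpatient_days_1y >= 0 & ind$inpatient_days_1y <= 365))
  expect_false(any(ind$home_90 & ind$institutionalized_90))
  expect_true(all(ind$died_1y[ind$died_90]))
})
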