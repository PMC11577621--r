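# minimal indicator-like table for direct DID tests
did_rows <- function(y, treat, post, year = NULL, extra = list()) {
  dt <- data.table::data.table(
    y = y,
    region = ifelse(treat == 1, "treated_city", "rest_country"),
    cohort_year = if (is.null(year)) ifelse(post == 1, 2008L, 2002L)
                  else year)
  for (nm in names(extra)) dt[[nm]] <- extra[[nm]]
  dt
}

spec_nocov <- function(outcome = "y", pre = 2002L, post = 2008L,
                       excluded = integer(), ...) {
  did_spec(outcome, "treated_city", "rest_country", pre, post, excluded,
           covariates = character(), ...)
}

test_that("spec validation rejects overlapping years and region sets", {
  expect_error(did_spec("y", "treated_city", "rest_country", 2001:2005,
                        2005:2008), "disjoint")
  expect_error(did_spec("y", "treated_city", "rest_country", 2001:2004,
                        2007:2008, excluded_years = 2003L), "excluded_years")
  expect_error(did_spec("y", "treated_city", "treated_city", 2001:2004,
                        2007:2008), "disjoint")
})

test_that("DID on balanced cells without covariates is the cell-mean identity", {
  set.seed(1)
  treat <- rep(c(0, 0, 1, 1), each = 20)
  post <- rep(c(0, 1, 0, 1), each = 20)
  y <- c(rep(10, 20), rep(12, 20), rep(10, 20), rep(15, 20)) + rnorm(80)
  d <- did_rows(y, treat, post)
  cm <- tapply(y, list(treat, post), mean)
  oracle <- (cm["1", "1"] - cm["1", "0"]) - (cm["0", "1"] - cm["0", "0"])
  r <- fit_did_ols(d, spec_nocov())
  expect_equal(r$estimate, oracle, tolerance = 1e-12)
  r2 <- fit_did_ols(d, spec_nocov(time_structure = "prepost"))
  expect_equal(r2$estimate, oracle, tolerance = 1e-12)
})

test_that("a degenerate outcome yields a zero estimate with a warning", {
  d <- did_rows(rep(5, 80), rep(c(0, 1), 40), rep(c(0, 0, 1, 1), 20))
  expect_warning(r <- fit_did_ols(d, spec_nocov()), "degenerate")
  expect_equal(r$estimate, 0)
})

test_that("an empty 2x2 cell errors naming the cell", {
  d <- did_rows(rnorm(60), treat = rep(c(0, 0, 1), 20),
                post = rep(c(0, 1, 0), 20))
  expect_error(fit_did_ols(d, spec_nocov()), "treated/post")
})

test_that("DID estimates are translation invariant and scale equivariant", {
  set.seed(2)
  n <- 400
  d <- did_rows(rnorm(n, 10), treat = rbinom(n, 1, 0.4),
                post = rbinom(n, 1, 0.5),
                extra = list(age = rnorm(n, 70, 10)))
  sp <- did_spec("y", "treated_city", "rest_country", 2002L, 2008L,
                 covariates = "age")
  r0 <- fit_did_ols(d, sp)
  d2 <- data.table::copy(d); d2$y <- d2$y + 100
  expect_equal(fit_did_ols(d2, sp)$estimate, r0$estimate, tolerance = 1e-9)
  d3 <- data.table::copy(d); d3$y <- d3$y * -2.5
  expect_equal(fit_did_ols(d3, sp)$estimate, -2.5 * r0$estimate,
               tolerance = 1e-9)
})

test_that("excluded implementation years are dropped before fitting", {
  set.seed(3)
  y <- rnorm(300)
  yr <- sample(c(2002L, 2006L, 2008L), 300, replace = TRUE)
  d <- did_rows(y, rbinom(300, 1, 0.5), as.integer(yr == 2008L), year = yr)
  r <- fit_did_ols(d, spec_nocov(excluded = 2006L))
  expect_equal(r$n_used, sum(yr != 2006L))
})

test_that("baseline marginals with no covariates reproduce raw group means", {
  set.seed(4)
  d <- did_rows(y = rbinom(300, 1, 0.3), treat = rbinom(300, 1, 0.5),
                post = 0)
  sp <- spec_nocov()
  m <- baseline_marginals(d, sp, family = "binomial")
  raw <- tapply(d$y, d$region, mean)
  expect_equal(m$marginal_treated, unname(raw["treated_city"]),
               tolerance = 1e-6)
  expect_equal(m$marginal_control, unname(raw["rest_country"]),
               tolerance = 1e-6)
  # continuous outcome, gaussian family
  d2 <- did_rows(y = rnorm(300, 50, 5), treat = rbinom(300, 1, 0.5), post = 0)
  m2 <- baseline_marginals(d2, sp, family = "gaussian")
  raw2 <- tapply(d2$y, d2$region, mean)
  expect_equal(m2$marginal_treated, unname(raw2["treated_city"]),
               tolerance = 1e-6)
})

test_that("baseline marginals recover generating probabilities with covariates", {
  set.seed(6)
  n <- 5000
  treat <- rbinom(n, 1, 0.5)
  p <- ifelse(treat == 1, 0.12, 0.17)
  d <- did_rows(y = rbinom(n, 1, p), treat = treat, post = 0,
                extra = list(age = rnorm(n, 70, 10),
                             sex = sample(c("male", "female"), n, TRUE)))
  sp <- did_spec("y", "treated_city", "rest_country", 2002L, 2008L,
                 covariates = c("age", "sex"))
  m <- baseline_marginals(d, sp)
  expect_equal(m$family, "binomial")
  se1 <- sqrt(0.12 * 0.88 / sum(treat == 1))
  se0 <- sqrt(0.17 * 0.83 / sum(treat == 0))
  expect_lt(abs(m$marginal_treated - 0.12), 3 * se1)
  expect_lt(abs(m$marginal_control - 0.17), 3 * se0)
})

test_that("parallel-trend test requires 3 pre years and reports all four families", {
  set.seed(7)
  n <- 900
  yr <- sample(2001:2003, n, replace = TRUE)
  d <- did_rows(rnorm(n, 10 + 0.5 * (yr - 2001)), rbinom(n, 1, 0.4),
                post = 0, year = yr)
  sp <- did_spec("y", "treated_city", "rest_country", 2001:2003, 2008L,
                 covariates = character())
  tt <- test_parallel_trends(d, sp)
  expect_setequal(tt$family, c("annual", "linear", "logarithmic",
                               "quadratic"))
  expect_true(all(tt$p_value >= 0 & tt$p_value <= 1))
  d1 <- d[yr == 2001]
  sp1 <- did_spec("y", "treated_city", "rest_country", 2001L, 2008L,
                  covariates = character())
  expect_error(test_parallel_trends(d1, sp1), "3 distinct pre-period years")
})

test_that("parallel-trend joint test holds its size under common trends", {
  set.seed(8)
  rej <- vapply(1:100, function(i) {
    n <- 450
    yr <- sample(2001:2003, n, replace = TRUE)
    tr <- rbinom(n, 1, 0.4)
    d <- did_rows(rnorm(n, 5 + 1.0 * (yr - 2001)), tr, post = 0, year = yr)
    sp <- did_spec("y", "treated_city", "rest_country", 2001:2003, 2008L,
                   covariates = character())
    attr(test_parallel_trends(d, sp), "annual_p") < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.005)
  expect_lt(mean(rej), 0.13)
})

test_that("kernel weights are non-negative, vanish off support, and flatten as bandwidth grows", {
  set.seed(9)
  p <- c(runif(50, 0.1, 0.4), runif(50, 0.35, 0.9))
  tr <- rep(c(1, 0), each = 50)
  w <- strokebench:::kernel_match_weights(p, tr, 0.06)
  expect_true(all(w >= 0))
  expect_true(all(w[tr == 1] == 1))
  off <- p > 0.4 + 0.06 # farther than one bandwidth from any treated score
  expect_true(all(w[tr == 0][off[tr == 0]] == 0))
  on <- w[tr == 0] > 0
  expect_equal(mean(w[tr == 0][on]), 1, tolerance = 1e-12)
  w_inf <- strokebench:::kernel_match_weights(p, tr, 1e6)
  expect_equal(w_inf, rep(1, 100), tolerance = 1e-9)
})

test_that("with identical propensity scores kernel-matched DID equals plain OLS", {
  set.seed(10)
  n <- 400
  d <- did_rows(rnorm(n, 20, 4), rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
  sp <- spec_nocov()
  ols <- fit_did_ols(d, sp)
  km <- kernel_psm_did(d, sp, bandwidth = 0.06, n_boot = 50, seed = 1)
  expect_lt(abs(km$estimate - ols$estimate), 1e-8)
  expect_equal(km$off_support, 0L)
})

test_that("bootstrap standard errors are deterministic given the seed", {
  set.seed(12)
  n <- 300
  d <- did_rows(rnorm(n, 20, 4), rbinom(n, 1, 0.5), rbinom(n, 1, 0.5),
                extra = list(age = rnorm(n, 70, 8)))
  sp <- did_spec("y", "treated_city", "rest_country", 2002L, 2008L,
                 covariates = "age")
  a <- kernel_psm_did(d, sp, n_boot = 120, seed = 33)
  b <- kernel_psm_did(d, sp, n_boot = 120, seed = 33)
  cc <- kernel_psm_did(d, sp, n_boot = 120, seed = 34)
  expect_identical(a$se, b$se)
  expect_identical(a$p_value, b$p_value)
  expect_false(identical(a$se, cc$se))
})

test_that("kernel matching corrects time-varying composition confounding better than unadjusted OLS", {
  # comorbidity prevalence differs by region and its effect doubles in the
  # post period, so the unadjusted DID absorbs a composition artefact; the
  # covariates carry the signal the matching needs
  set.seed(14)
  wins <- vapply(1:10, function(i) {
    n <- 1200
    cb <- rbinom(n, 1, 0.4)
    pr <- plogis(-1 + 1.6 * cb)
    tr <- rbinom(n, 1, pr)
    post <- rbinom(n, 1, 0.5)
    y <- 10 + 3 * cb + 4 * cb * post + rnorm(n, 0, 2) # true effect is 0
    d <- did_rows(y, tr, post, extra = list(cb01 = cb))
    sp_cov <- did_spec("y", "treated_city", "rest_country", 2002L, 2008L,
                       covariates = "cb01")
    naive <- fit_did_ols(d, spec_nocov())
    km <- kernel_psm_did(d, sp_cov, n_boot = 30, seed = i)
    abs(km$estimate) < abs(naive$estimate)
  }, logical(1))
  expect_gte(sum(wins), 7)
})
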