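#' Specification of a difference-in-difference comparison
#'
#' Defines one DID contrast: the outcome, the treated and control region
#' sets, pre- and post-intervention cohort years, implementation years
#' excluded from the fit (effects were phased in, so the first post-reform
#' year is dropped), and the risk-adjustment covariates.
#'
#' @param outcome Indicator column name.
#' @param treat_regions,control_regions Disjoint subsets of
#'   [region_levels()].
#' @param pre_years,post_years Disjoint integer vectors of cohort years.
#' @param excluded_years Years dropped before fitting (default none); must
#'   not intersect `pre_years` or `post_years`.
#' @param covariates Covariate column names (default [default_covariates()]).
#' @param time_structure `"years"` (year indicators alongside the single
#'   treat-by-post interaction; default) or `"prepost"` (a single post
#'   dummy).
#' @return Object of class `did_spec`.
#' @export
did_spec <- function(outcome, treat_regions, control_regions,
                     pre_years, post_years, excluded_years = integer(),
                     covariates = default_covariates(),
                     time_structure = c("years", "prepost")) {
  time_structure <- match.arg(time_structure)
  if (length(intersect(pre_years, post_years)))
    stopf("pre_years and post_years must be disjoint")
  if (length(intersect(excluded_years, c(pre_years, post_years))))
    stopf("excluded_years must not overlap pre_years or post_years")
  if (length(intersect(treat_regions, control_regions)))
    stopf("treat and control region sets must be disjoint")
  structure(list(outcome = outcome,
                 treat_regions = treat_regions,
                 control_regions = control_regions,
                 pre_years = as.integer(pre_years),
                 post_years = as.integer(post_years),
                 excluded_years = as.integer(excluded_years),
                 covariates = covariates,
                 time_structure = time_structure),
            class = "did_spec")
}

# Assemble the estimation frame for a did_spec: filters regions and years,
# codes treat/post/did, and drops covariates that are constant in the
# analysis sample (they carry no information and break the fit).
did_data <- function(rows, spec) {
  dt <- data.table::as.data.table(rows)
  if (!spec$outcome %in% names(dt))
    stopf("outcome column '%s' not found", spec$outcome)
  dt <- dt[region %in% c(spec$treat_regions, spec$control_regions) &
             cohort_year %in% c(spec$pre_years, spec$post_years)]
  covs <- intersect(spec$covariates, names(dt))
  d <- data.table::data.table(
    y = as.numeric(dt[[spec$outcome]]),
    treat = as.numeric(dt$region %in% spec$treat_regions),
    post = as.numeric(dt$cohort_year %in% spec$post_years),
    yearf = factor(dt$cohort_year))
  d[, did := treat * post]
  for (cv in covs) {
    v <- dt[[cv]]
    if (is.logical(v)) v <- as.numeric(v)
    if (length(unique(v)) > 1L) d[[cv]] <- v
  }
  d <- d[!is.na(y)]
  cells <- table(factor(d$treat, levels = 0:1),
                 factor(d$post, levels = 0:1))
  if (any(cells == 0L)) {
    lab <- outer(c("control", "treated"), c("pre", "post"), paste, sep = "/")
    stopf("empty cell in 2x2 design: %s",
          paste(lab[cells == 0L], collapse = ", "))
  }
  d
}

did_covariate_terms <- function(d) {
  setdiff(names(d), c("y", "treat", "post", "yearf", "did"))
}

#' Covariate-adjusted OLS difference-in-difference estimate
#'
#' Fits, on individual-level data restricted to the pre and post cohorts of
#' the two region sets (implementation years excluded), the linear model
#' `outcome ~ treat + year indicators + treat x post + covariates` and
#' returns the treat-by-post coefficient with heteroskedasticity-consistent
#' (HC1) standard errors. Binary outcomes are modelled linearly (a linear
#' probability model): a nonlinear model inside the DID contrast would not
#' identify the effect consistently.
#'
#' @param rows Indicator table from [compute_indicators()].
#' @param spec A [did_spec()].
#' @return Object of class `did_result` with `estimate`, `se`, `p_value`,
#'   `method = "ols"` and `n_used`.
#' @export
fit_did_ols <- function(rows, spec) {
  d <- did_data(rows, spec)
  if (var(d$y) == 0) {
    warnf("outcome '%s' is degenerate (zero variance)", spec$outcome)
    return(did_result(0, NA_real_, NA_real_, "ols", nrow(d), spec))
  }
  f <- did_formula(d, spec)
  fit <- lm(f, data = d)
  V <- sandwich::vcovHC(fit, type = "HC1")
  est <- unname(coef(fit)["did"])
  se <- sqrt(V["did", "did"])
  p <- 2 * pt(-abs(est / se), df = fit$df.residual)
  did_result(est, se, p, "ols", nrow(d), spec)
}

did_formula <- function(d, spec) {
  covs <- did_covariate_terms(d)
  time_term <- if (spec$time_structure == "years" &&
                   nlevels(droplevels(d$yearf)) > 1L) "yearf" else "post"
  as.formula(paste("y ~ treat +", time_term, "+ did",
                   if (length(covs)) paste("+", paste(covs, collapse = " + "))
                   else ""))
}

did_result <- function(estimate, se, p_value, method, n_used, spec,
                       extra = list()) {
  structure(c(list(estimate = estimate, se = se, p_value = p_value,
                   method = method, n_used = n_used,
                   outcome = spec$outcome), extra),
            class = "did_result")
}

#' @export
print.did_result <- function(x, ...) {
  cat(sprintf("DID estimate [%s, %s]: %.4g (SE %.4g, p = %.4g%s) n = %d\n",
              x$outcome, x$method, x$estimate, x$se, x$p_value,
              paste0(" ", p_stars(x$p_value)), x$n_used))
  invisible(x)
}

#' Adjusted baseline (pre-period) marginal means per group
#'
#' Fits the outcome-appropriate model on pre-period data (logistic for
#' dichotomous outcomes, negative binomial for counts, gamma with log link
#' for positive continuous costs) with a treated-region dummy, year
#' indicators and covariates, and reports the average marginal mean per
#' group (predictions with the group dummy set to each value, averaged over
#' the sample) together with the p-value of the group dummy.
#'
#' @param rows Indicator table.
#' @param spec A [did_spec()]; only its pre-period and region sets are used.
#' @param family `"auto"` (detect from the outcome), `"binomial"`,
#'   `"negbin"`, `"gamma"` or `"gaussian"`.
#' @return List with `marginal_treated`, `marginal_control`, `p_value`,
#'   `family`, `n`.
#' @export
baseline_marginals <- function(rows, spec,
                               family = c("auto", "binomial", "negbin",
                                          "gamma", "gaussian")) {
  family <- match.arg(family)
  pre_spec <- spec
  pre_spec$post_years <- integer()
  dt <- data.table::as.data.table(rows)
  dt <- dt[region %in% c(spec$treat_regions, spec$control_regions) &
             cohort_year %in% spec$pre_years]
  if (nrow(dt) == 0L) stopf("no pre-period rows")
  y <- dt[[spec$outcome]]
  if (family == "auto") family <- detect_family(y)
  d <- data.table::data.table(y = as.numeric(y),
                              treat = as.numeric(dt$region %in%
                                                   spec$treat_regions),
                              yearf = factor(dt$cohort_year))
  for (cv in intersect(spec$covariates, names(dt))) {
    v <- dt[[cv]]
    if (is.logical(v)) v <- as.numeric(v)
    if (length(unique(v)) > 1L) d[[cv]] <- v
  }
  covs <- setdiff(names(d), c("y", "treat", "yearf"))
  rhs <- paste(c("treat",
                 if (nlevels(droplevels(d$yearf)) > 1L) "yearf",
                 covs), collapse = " + ")
  f <- as.formula(paste("y ~", rhs))
  fit <- fit_family(f, d, family)
  family <- attr(fit, "family_used") %||% family
  sm <- summary(fit)$coefficients
  p <- sm["treat", ncol(sm)]
  d1 <- data.table::copy(d); d1[, treat := 1]
  d0 <- data.table::copy(d); d0[, treat := 0]
  list(marginal_treated = mean(predict(fit, newdata = d1, type = "response")),
       marginal_control = mean(predict(fit, newdata = d0, type = "response")),
       p_value = unname(p), family = family, n = nrow(d))
}

detect_family <- function(y) {
  if (is.logical(y) || all(y %in% c(0, 1))) return("binomial")
  if (is.integer(y) || all(abs(y - round(y)) < 1e-9)) {
    if (all(y >= 0)) return("negbin")
  }
  if (all(y > 0)) return("gamma")
  "gaussian"
}

# Fit the requested family with graceful degradation: the negative binomial
# falls back to Poisson when the dispersion estimate diverges (the Poisson
# limit), and gamma falls back to gaussian when non-positive values occur.
fit_family <- function(f, d, family) {
  fit <- switch(family,
    binomial = glm(f, data = d, family = binomial()),
    negbin = tryCatch(
      suppressWarnings(MASS::glm.nb(f, data = d)),
      error = function(e) {
        g <- glm(f, data = d, family = poisson())
        attr(g, "family_used") <- "poisson"
        g
      }),
    gamma = if (all(d$y > 0)) glm(f, data = d, family = Gamma(link = "log"))
            else {
              g <- lm(f, data = d)
              attr(g, "family_used") <- "gaussian"
              g
            },
    gaussian = lm(f, data = d),
    stopf("unknown family '%s'", family))
  fit
}

#' Pre-period test of the common (parallel) trend assumption
#'
#' On pre-intervention cohorts only, fits OLS models explaining the outcome
#' by the intervention-area dummy and covariates plus (a) annual year
#' indicators, (b) a linear, (c) a logarithmic and (d) a quadratic time
#' trend, each interacted with the area dummy, and reports the joint F-test
#' p-value of the interaction terms per family. A small interaction p-value
#' signals diverging pre-trends, i.e. evidence against the common-trend
#' assumption.
#'
#' @param rows Indicator table (pre-period rows are selected internally).
#' @param spec A [did_spec()]; needs at least 3 distinct pre-period years.
#' @return data.table of class `trend_test` with columns `family`,
#'   `p_value`, `verdict`; attributes `annual_p`, `trend_p` (smallest of the
#'   three parametric trends) and `trend_verdict`.
#' @export
test_parallel_trends <- function(rows, spec) {
  dt <- data.table::as.data.table(rows)
  dt <- dt[region %in% c(spec$treat_regions, spec$control_regions) &
             cohort_year %in% spec$pre_years]
  yrs <- sort(unique(dt$cohort_year))
  if (length(yrs) < 3L)
    stopf("parallel-trend test needs >= 3 distinct pre-period years (got %d)",
          length(yrs))
  d <- data.table::data.table(
    y = as.numeric(dt[[spec$outcome]]),
    treat = as.numeric(dt$region %in% spec$treat_regions),
    yearf = factor(dt$cohort_year),
    t = dt$cohort_year - min(yrs) + 1)
  d[, `:=`(lt = log(t), t2 = t^2)]
  for (cv in intersect(spec$covariates, names(dt))) {
    v <- dt[[cv]]
    if (is.logical(v)) v <- as.numeric(v)
    if (length(unique(v)) > 1L) d[[cv]] <- v
  }
  covs <- setdiff(names(d), c("y", "treat", "yearf", "t", "lt", "t2"))
  covtail <- if (length(covs)) paste("+", paste(covs, collapse = " + ")) else ""
  jtest <- function(base_terms, inter_terms) {
    f0 <- as.formula(paste("y ~", paste(base_terms, collapse = " + "),
                           covtail))
    f1 <- as.formula(paste("y ~", paste(c(base_terms, inter_terms),
                                        collapse = " + "), covtail))
    a <- anova(lm(f0, data = d), lm(f1, data = d))
    a[2, "Pr(>F)"]
  }
  res <- data.table::data.table(
    family = c("annual", "linear", "logarithmic", "quadratic"),
    p_value = c(
      jtest(c("treat", "yearf"), "treat:yearf"),
      jtest(c("treat", "t"), "treat:t"),
      jtest(c("treat", "lt"), "treat:lt"),
      jtest(c("treat", "t", "t2"), c("treat:t", "treat:t2"))))
  res[, verdict := p_stars(p_value)]
  trend_p <- min(res$p_value[res$family != "annual"])
  data.table::setattr(res, "annual_p", res$p_value[res$family == "annual"])
  data.table::setattr(res, "trend_p", trend_p)
  data.table::setattr(res, "trend_verdict", p_stars(trend_p))
  data.table::setattr(res, "class", c("trend_test", class(res)))
  res[]
}

#' Kernel propensity-score-matched DID with bootstrapped standard errors
#'
#' Sensitivity analysis combining the DID contrast with kernel propensity
#' matching: the propensity of treated-region membership is estimated by
#' logistic regression on the covariates; each control observation is
#' weighted by the average Epanechnikov kernel distance
#' `K(u) = 0.75 (1 - u^2), |u| < 1`, `u = (p_control - p_treated) /
#' bandwidth`, over all treated observations, weights normalized to mean one
#' within the on-support control group (treated weights are one; controls
#' with zero kernel mass are off support and dropped with a logged count).
#' The weighted OLS DID gives the estimate; its standard error and p-value
#' come from resampling patients with replacement, re-estimating propensity
#' and weights in every bootstrap replicate.
#'
#' @param rows Indicator table.
#' @param spec A [did_spec()].
#' @param bandwidth Kernel bandwidth on the propensity scale (default 0.06).
#' @param n_boot Bootstrap replicates (default 5000). With at least 1000
#'   replicates the p-value is the two-sided percentile probability of the
#'   bootstrap distribution crossing zero; below that a normal approximation
#'   `2 pnorm(-|estimate| / se_boot)` is used.
#' @param seed Seed for the bootstrap resampling.
#' @return A `did_result` with `method = "kernel_psm_bootstrap"`, the number
#'   of off-support controls (`off_support`), `n_boot` and `seed`.
#' @export
kernel_psm_did <- function(rows, spec, bandwidth = 0.06, n_boot = 5000L,
                           seed = 1L) {
  if (bandwidth <= 0) stopf("bandwidth must be positive")
  d <- did_data(rows, spec)
  f <- did_formula(d, spec)
  Z <- model.matrix(f, data = d)
  y <- d$y
  tr <- d$treat
  covs <- did_covariate_terms(d)
  X <- if (length(covs)) {
    model.matrix(as.formula(paste("~", paste(covs, collapse = " + "))),
                 data = d)
  } else matrix(1, nrow(d), 1L)
  n <- nrow(d)
  didcol <- match("did", colnames(Z))

  estimate_once <- function(idx, strict = FALSE) {
    ti <- tr[idx]
    if (ncol(X) == 1L) {
      p <- rep(mean(ti), length(idx))
    } else {
      g <- suppressWarnings(glm.fit(X[idx, , drop = FALSE], ti,
                                    family = binomial()))
      if (strict && !g$converged)
        stopf("propensity model did not converge")
      p <- g$fitted.values
    }
    w <- kernel_match_weights(p, ti, bandwidth)
    if (all(w[ti == 0] == 0)) {
      if (strict) stopf("all control observations off support")
      return(c(NA_real_, NA_real_))
    }
    b <- lm.wfit(Z[idx, , drop = FALSE], y[idx], w)$coefficients[didcol]
    c(b, sum(w[ti == 0] == 0))
  }

  main <- estimate_once(seq_len(n), strict = TRUE)
  est <- unname(main[1L])
  off_support <- as.integer(main[2L])

  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    estimate_once(sample.int(n, n, replace = TRUE))[1L]
  }, numeric(1))
  ok <- !is.na(boots)
  se <- sd(boots[ok])
  p <- if (n_boot >= 1000L) {
    2 * min(mean(boots[ok] < 0), mean(boots[ok] > 0))
  } else {
    2 * pnorm(-abs(est / se))
  }
  did_result(est, se, min(1, p), "kernel_psm_bootstrap", n, spec,
             extra = list(off_support = off_support, n_boot = n_boot,
                          seed = seed, bandwidth = bandwidth,
                          boot_ok = sum(ok)))
}

# Epanechnikov kernel weights for controls against the treated propensity
# distribution; computed in blocks so the n_control x n_treated distance
# matrix never materializes for large registers.
kernel_match_weights <- function(p, treat01, bandwidth) {
  ic <- which(treat01 == 0)
  it <- which(treat01 == 1)
  pt_ <- p[it]
  w <- rep(1, length(p))
  nc <- length(ic)
  if (nc == 0L || length(it) == 0L) return(w)
  wc <- numeric(nc)
  block <- max(1L, as.integer(2e7 / max(1L, length(it))))
  for (s in seq(1L, nc, by = block)) {
    e <- min(nc, s + block - 1L)
    U <- outer(p[ic[s:e]], pt_, "-") / bandwidth
    K <- 0.75 * (1 - U^2)
    K[abs(U) >= 1] <- 0
    wc[s:e] <- rowMeans(K)
  }
  on <- wc > 0
  if (any(on)) wc[on] <- wc[on] / mean(wc[on])
  w[ic] <- wc
  w
}
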