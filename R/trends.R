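#' Rolling-cohort window specification
#'
#' The figure methodology refits the indicator models on overlapping
#' 365-day cohorts advanced by 30 days: each window's cohort consists of
#' patients whose index admission falls in `[start, start + span)`.
#'
#' @param first_start,last_start First and last window start dates.
#' @param step Days between consecutive window starts (default 30).
#' @param span Window length in days (default 365).
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(first_start, last_start, step = 30L, span = 365L) {
  first_start <- as.Date(first_start); last_start <- as.Date(last_start)
  if (last_start < first_start) stopf("last_start before first_start")
  if (step < 1L) stopf("step must be >= 1 day")
  if (span < 1L) stopf("span must be >= 1 day")
  structure(list(first_start = first_start, last_start = last_start,
                 step = as.integer(step), span = as.integer(span)),
            class = "window_spec")
}

#' Enumerate rolling windows
#'
#' Window starts are `first_start + k * step` for `k = 0, 1, ...` while the
#' start does not exceed `last_start`; the count is
#' `floor((last_start - first_start) / step) + 1`.
#'
#' @param ws A [window_spec()].
#' @return data.table with `window_id`, `start`, `end` (exclusive).
#' @export
enumerate_windows <- function(ws) {
  k <- 0:((as.integer(ws$last_start) - as.integer(ws$first_start)) %/% ws$step)
  starts <- ws$first_start + k * ws$step
  data.table::data.table(window_id = seq_along(starts), start = starts,
                         end = starts + ws$span)
}

# Default model family per indicator; falls back to detection by value.
outcome_family <- function(outcome, y = NULL) {
  fam <- c(home_90 = "binomial", institutionalized_90 = "binomial",
           died_90 = "binomial", died_1y = "binomial",
           acute_los = "negbin", episode_los = "negbin",
           inpatient_days_1y = "negbin",
           episode_cost = "gamma", cost_1y = "gamma")[outcome]
  if (!is.na(fam)) return(unname(fam))
  if (is.null(y)) "gaussian" else detect_family(y)
}

#' Adjusted marginal estimates per region for one cohort window
#'
#' Fits the outcome-appropriate model (logistic for dichotomous outcomes,
#' negative binomial for counts, gamma log-link for costs) with region
#' dummies and covariates, and returns the average marginal estimate per
#' region: predictions with every observation assigned to that region,
#' averaged over the sample, with delta-method standard errors.
#'
#' @param rows Indicator rows of one window.
#' @param outcome Indicator column name.
#' @param regions Region levels to estimate (default all three).
#' @param covariates Covariate columns (default [default_covariates()]).
#' @param family Model family, `"auto"` to choose by outcome.
#' @return data.table with `region`, `estimate`, `se`, `n`.
#' @export
fit_window <- function(rows, outcome, regions = region_levels(),
                       covariates = default_covariates(), family = "auto") {
  dt <- data.table::as.data.table(rows)
  dt <- dt[region %in% regions]
  if (nrow(dt) == 0L) stopf("no rows in window")
  y <- dt[[outcome]]
  if (family == "auto") family <- outcome_family(outcome, y)
  d <- data.table::data.table(y = as.numeric(y),
                              regionf = factor(dt$region, levels = regions))
  d[, regionf := droplevels(regionf)]
  for (cv in intersect(covariates, names(dt))) {
    v <- dt[[cv]]
    if (is.logical(v)) v <- as.numeric(v)
    if (length(unique(v)) > 1L) d[[cv]] <- v
  }
  covs <- setdiff(names(d), c("y", "regionf"))
  rhs <- paste(c(if (nlevels(d$regionf) > 1L) "regionf", covs, "1"),
               collapse = " + ")
  f <- as.formula(paste("y ~", rhs))
  if (var(d$y) == 0) {
    # constant outcome: every adjusted marginal equals that constant
    cnt <- table(factor(dt$region, levels = regions))
    return(data.table::data.table(region = regions, estimate = d$y[1],
                                  se = 0, n = as.integer(cnt[regions])))
  }
  fit <- fit_family(f, d, family)
  b <- coef(fit)
  keep <- !is.na(b)
  V <- vcov(fit)
  is_glm <- inherits(fit, "glm")
  res <- lapply(regions, function(r) {
    dr <- data.table::copy(d)
    dr[, regionf := factor(r, levels = levels(d$regionf))]
    X <- model.matrix(stats::delete.response(stats::terms(fit)), data = dr)
    X <- X[, names(b)[keep], drop = FALSE]
    eta <- as.numeric(X %*% b[keep])
    if (is_glm) {
      mu <- fit$family$linkinv(eta)
      grad <- colMeans(fit$family$mu.eta(eta) * X)
    } else {
      mu <- eta
      grad <- colMeans(X)
    }
    se <- sqrt(as.numeric(t(grad) %*% V[names(b)[keep], names(b)[keep]] %*%
                            grad))
    data.table::data.table(region = r, estimate = mean(mu), se = se)
  })
  out <- data.table::rbindlist(res)
  cnt <- table(factor(dt$region, levels = regions))
  out[, n := as.integer(cnt[region])]
  out[]
}

#' Build adjusted marginal-effect trend series over rolling cohorts
#'
#' Iterates [fit_window()] over every window and outcome. A patient belongs
#' to every window containing their index date, so consecutive windows
#' overlap by construction. Windows with too few observations in a region,
#' or where the model fails, are flagged and kept in the series with missing
#' estimates rather than silently dropped.
#'
#' @param rows Indicator table with `index_date`.
#' @param ws A [window_spec()].
#' @param outcomes Indicator columns to model.
#' @param regions Regions to report.
#' @param covariates Covariate columns.
#' @param min_per_region Minimum observations per region required to fit a
#'   window (default 10).
#' @return Long data.table with `window_id`, `window_start`, `outcome`,
#'   `region`, `estimate`, `se`, `n`, `flag` (`""`, `"insufficient"`, or
#'   `"fit_failed"`).
#' @export
build_trend_series <- function(rows, ws, outcomes,
                               regions = region_levels(),
                               covariates = default_covariates(),
                               min_per_region = 10L) {
  dt <- data.table::as.data.table(rows)
  wins <- enumerate_windows(ws)
  out <- vector("list", nrow(wins) * length(outcomes))
  k <- 0L
  for (w in seq_len(nrow(wins))) {
    sub <- dt[index_date >= wins$start[w] & index_date < wins$end[w] &
                region %in% regions]
    cnt <- table(factor(sub$region, levels = regions))
    for (oc in outcomes) {
      k <- k + 1L
      if (any(cnt < min_per_region)) {
        out[[k]] <- data.table::data.table(
          window_id = wins$window_id[w], window_start = wins$start[w],
          outcome = oc, region = regions, estimate = NA_real_,
          se = NA_real_, n = as.integer(cnt[regions]), flag = "insufficient")
        next
      }
      fitted <- tryCatch(
        fit_window(sub, oc, regions, covariates),
        error = function(e) NULL)
      out[[k]] <- if (is.null(fitted)) {
        data.table::data.table(
          window_id = wins$window_id[w], window_start = wins$start[w],
          outcome = oc, region = regions, estimate = NA_real_,
          se = NA_real_, n = as.integer(cnt[regions]), flag = "fit_failed")
      } else {
        data.table::data.table(
          window_id = wins$window_id[w], window_start = wins$start[w],
          outcome = oc, region = fitted$region, estimate = fitted$estimate,
          se = fitted$se, n = fitted$n, flag = "")
      }
    }
  }
  data.table::rbindlist(out)
}
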