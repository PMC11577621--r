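#' @import data.table
#' @importFrom stats anova as.formula binomial coef glm glm.fit Gamma gaussian
#'   lm lm.wfit median model.matrix pnorm poisson predict pt quantile rbinom
#'   rgamma rgeom rnorm runif sd setNames uniroot var vcov plogis qlogis
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Day difference with a floor of one day
#'
#' Lengths of stay are `end - start` in days with same-day discharges counted
#' as one day, so count models never see zero-length episodes.
#'
#' @param start,end `Date` vectors.
#' @return Integer days, minimum 1.
#' @keywords internal
days_len <- function(start, end) {
  pmax(1L, as.integer(end) - as.integer(start))
}

# Days a stay contributes inside a half-open window [w0, w1).
# Same-day stays (discharge == admit) occupy one day.
stay_days_window <- function(admit, discharge, w0, w1) {
  a <- as.integer(admit)
  d <- pmax(as.integer(discharge), a + 1L)
  pmax(0L, pmin(d, as.integer(w1)) - pmax(a, as.integer(w0)))
}

# Total days covered by the union of stay intervals, clipped to [w0, w1).
# Same-day stays are widened to one day before merging.
interval_union_days <- function(admit, discharge, w0, w1) {
  a <- pmax(as.integer(admit), as.integer(w0))
  d <- pmin(pmax(as.integer(discharge), as.integer(admit) + 1L), as.integer(w1))
  keep <- d > a
  if (!any(keep)) return(0L)
  a <- a[keep]; d <- d[keep]
  o <- order(a, d)
  a <- a[o]; d <- d[o]
  dmax <- cummax(d)
  # a new block starts where the next interval begins after the running end
  starts <- c(TRUE, a[-1] > dmax[-length(dmax)])
  block <- cumsum(starts)
  sum(vapply(split(seq_along(a), block), function(i) {
    max(d[i]) - min(a[i])
  }, integer(1)))
}

# Shift delta such that mean(plogis(eta + delta)) == target on this sample.
# Used by the register generator to hit cell-level probability targets exactly
# in expectation while keeping covariate heterogeneity on the log-odds scale.
calibrate_logit_probs <- function(eta, target) {
  n <- length(eta)
  if (n == 0L) return(numeric(0))
  if (target <= 0) return(rep(0, n))
  if (target >= 1) return(rep(1, n))
  if (all(abs(eta - eta[1]) < 1e-12)) return(rep(target, n))
  f <- function(d) mean(plogis(eta + d)) - target
  d <- uniroot(f, c(-30, 30), tol = 1e-10)$root
  plogis(eta + d)
}

# Draw mean m such that E[min(X, cap)] = target for X ~ Gamma(shape 2,
# mean m): fixed-point iteration on m = target + E[(X - cap)+], with the
# censored tail in closed form for shape-2 gamma.
gamma2_capped_mean <- function(target, cap) {
  trim <- function(m) {
    r <- 2 * cap / m
    e <- exp(-r)
    s2 <- (1 + r) * e
    s3 <- (1 + r + r^2 / 2) * e
    m * s3 - cap * s2
  }
  m <- target
  for (i in 1:4) m <- target + trim(m)
  m
}

# Significance stars at the conventional 5% / 1% / 0.1% levels.
p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
    ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

as_date <- function(x) as.Date(x, origin = "1970-01-01")

year_of <- function(d) as.integer(format(d, "%Y"))
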