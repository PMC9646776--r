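#' One step of the harvested logistic map
#'
#' The discrete surplus-production update for standardised spawning stock
#' biomass: \deqn{X_{t+1} = X_t + r X_t (1 - X_t / K_t) - \alpha X_t.}
#' The growth term pulls the stock toward the environmentally set carrying
#' capacity K; the removal term takes the fraction alpha of the current
#' biomass. No clamping or extirpation policy is applied here — callers
#' (\code{\link{simulateStock}}) own that. At K = 0 the growth term is
#' taken as its limit 0 and only the removal acts.
#'
#' @param x current dSSB (>= 0)
#' @param k carrying capacity (mdSSB, 0-1 scale)
#' @param r population growth rate per year, in (0, 1]
#' @param alpha fishing intensity (fraction of dSSB removed), in [0, 1]
#' @return next-year dSSB (possibly negative; caller clamps)
#' @examples
#' stepStock(0.5, 1, 0.5, 0)      # 0.625
#' stepStock(0.2, 0.4, 0.5, 0.1)  # 0.23
#' @export
stepStock <- function(x, k, r, alpha) {
  growth <- ifelse(k > 0, r * x * (1 - x / k), 0)
  x + growth - alpha * x
}

#' Closed-form equilibrium of the harvested logistic map
#'
#' With constant forcing the map has fixed point \eqn{K (1 - \alpha / r)},
#' floored at 0 once removal outpaces growth (alpha >= r).
#'
#' @inheritParams stepStock
#' @return equilibrium dSSB
#' @export
equilibriumDssb <- function(k, r, alpha) {
  pmax(0, k * (1 - alpha / r))
}

newTrajectory <- function(years, x, k, alpha, catch, r, extYear) {
  new("StockTrajectory", years = as.integer(years), x = x, k = k,
      alpha = alpha, catch = catch, r = r,
      extirpatedYear = as.integer(extYear))
}

# Shared iteration core. removalFun(x, t) returns the amount removed in
# year t given pre-step biomass x; alphaOut records the implied intensity.
iterateStock <- function(x0, kSeries, r, removalFun, alphaOut, years, config) {
  n <- length(kSeries)
  x <- numeric(n)
  catch <- numeric(n)
  extYear <- NA_integer_
  x[1] <- x0
  rule <- config@extirpationRuleEnabled
  thr <- config@extirpationThreshold
  if (rule && x[1] <= thr) {
    extYear <- years[1]
    x[1] <- 0
  }
  for (t in seq_len(n - 1L)) {
    if (!is.na(extYear)) {
      x[t + 1L] <- 0
      next
    }
    rem <- removalFun(x[t], t)
    catch[t] <- rem
    k <- kSeries[t]
    growth <- if (k > 0) r * x[t] * (1 - x[t] / k) else 0
    xn <- x[t] + growth - rem
    if (config@clampNegative && xn < 0) xn <- 0
    if (rule && xn <= thr) {
      extYear <- years[t + 1L]
      xn <- 0
    }
    x[t + 1L] <- xn
  }
  if (is.na(extYear) && n >= 1L) catch[n] <- removalFun(x[n], n)
  newTrajectory(years, x, kSeries, alphaOut, catch, r, extYear)
}

#' Simulate a harvested stock trajectory
#'
#' Iterates the harvested logistic map over aligned annual series of
#' carrying capacity and fishing intensity. Negative intermediate values
#' are clamped at 0 when \code{clampNegative} is on. With the extirpation
#' rule enabled, the first year in which dSSB falls to or below the
#' extirpation threshold sets the stock to 0 permanently (absorbing state)
#' and is recorded. The state is not capped at K: under a sudden drop in K
#' with light fishing, X can sit transiently above K.
#'
#' @param x0 initial dSSB (> 0)
#' @param kSeries annual mdSSB K_t
#' @param alphaSeries annual fishing intensity; a scalar is recycled
#' @param r population growth rate
#' @param config \linkS4class{DynamicsConfig}
#' @param years calendar years (default 1..n)
#' @return a \linkS4class{StockTrajectory}
#' @export
simulateStock <- function(x0, kSeries, alphaSeries, r,
                          config = dynamicsConfig(),
                          years = seq_along(kSeries)) {
  n <- length(kSeries)
  if (length(alphaSeries) == 1L) alphaSeries <- rep(alphaSeries, n)
  if (length(alphaSeries) == n - 1L) alphaSeries <- c(alphaSeries, alphaSeries[n - 1L])
  if (length(alphaSeries) != n)
    stop("alphaSeries must have length 1, n-1 or n to align with kSeries")
  if (length(years) != n) stop("years must align with kSeries")
  stopifnot(x0 > 0, r > 0)
  iterateStock(x0, kSeries, r,
               removalFun = function(x, t) alphaSeries[t] * x,
               alphaOut = alphaSeries, years = years, config = config)
}

#' Simulate under a constant standardised catch
#'
#' Same map as \code{\link{simulateStock}} but with a fixed annual removal
#' (a constant standardised catch, alpha X held constant) instead of a
#' fixed removal fraction. Used for the constant-catch projection
#' scenarios; the reference analysis uses catch = 0.03, the 2008-2019 mean.
#'
#' @inheritParams simulateStock
#' @param catch fixed annual standardised removal (>= 0); removal in a year
#'   is capped at the available biomass
#' @return a \linkS4class{StockTrajectory} (\code{alpha} holds the implied
#'   per-year intensity catch / x)
#' @export
simulateConstantCatch <- function(x0, kSeries, catch, r,
                                  config = dynamicsConfig(),
                                  years = seq_along(kSeries)) {
  stopifnot(catch >= 0, x0 > 0, r > 0)
  n <- length(kSeries)
  if (length(years) != n) stop("years must align with kSeries")
  traj <- iterateStock(x0, kSeries, r,
                       removalFun = function(x, t) min(catch, x),
                       alphaOut = rep(NA_real_, n), years = years,
                       config = config)
  alpha <- ifelse(traj@x > 0, traj@catch / traj@x, 0)
  newTrajectory(years, traj@x, kSeries, alpha, traj@catch, r,
                traj@extirpatedYear)
}

#' Years needed to rebuild a collapsed stock under a moratorium
#'
#' Iterates the unfished logistic map (alpha = 0) at constant carrying
#' capacity from a post-collapse state until the rebuilding target is
#' reached. The crossing step is linearly interpolated and the starting
#' year is counted, so the return value is the fractional number of years
#' including the year the moratorium starts. When the carrying capacity is
#' at or below the target the stock can never reach it and \code{Inf} is
#' returned.
#'
#' @param k constant mdSSB during recovery
#' @param r population growth rate
#' @param target rebuilding target dSSB (default 0.4)
#' @param x0 post-collapse starting dSSB (default 0.1)
#' @param maxYears iteration guard
#' @return fractional years to recovery (report rounded to 0.1), or Inf
#' @examples
#' round(recoveryTime(1, 0.5), 1)      # 5.1
#' round(recoveryTime(0.401, 0.25), 1) # 27.2
#' @export
recoveryTime <- function(k, r, target = 0.4, x0 = 0.1, maxYears = 1e5) {
  stopifnot(k >= 0, r > 0, x0 > 0)
  if (k <= target) return(Inf)
  if (x0 >= target) return(1)
  x <- x0
  n <- 0L
  repeat {
    xn <- x + r * x * (1 - x / k)
    n <- n + 1L
    if (xn >= target) {
      frac <- (n - 1L) + (target - x) / (xn - x)
      return(frac + 1)
    }
    x <- xn
    if (n > maxYears) stop("recovery did not converge within maxYears")
  }
}

#' Stock-collapse test
#'
#' A stock is collapsed when its dSSB is at or below a fraction of the
#' unfished biomass mdSSB (10 percent by default) — a relative rule: the
#' same absolute biomass can be collapsed under a rich environment and
#' healthy under a poor one.
#'
#' @param x dSSB
#' @param k mdSSB (unfished biomass)
#' @param config \linkS4class{DynamicsConfig}
#' @return logical
#' @export
isCollapsed <- function(x, k, config = dynamicsConfig()) {
  x <= config@collapseFraction * k
}
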