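#' Inverse estimation of fishing intensity from a biomass series
#'
#' Algebraic inversion of the harvested logistic map: given consecutive
#' dSSB values and the carrying capacity, the removal fraction that
#' produced the observed transition is
#' \deqn{\alpha_t = 1 + r (1 - X_t / K_t) - X_{t+1} / X_t.}
#' Estimates outside [0, 1] are returned as computed (they indicate model
#' misfit or data problems) with attribute \code{"flagged"} marking them.
#'
#' @param xSeries dSSB per year, strictly positive, length >= 2
#' @param kSeries mdSSB per year, aligned with \code{xSeries}
#' @param r population growth rate
#' @return alpha estimates of length \code{length(xSeries) - 1}, with a
#'   logical attribute \code{flagged} for values outside [0, 1]
#' @examples
#' estimateAlpha(c(0.2, 0.23), 0.4, 0.5)  # 0.1
#' @export
estimateAlpha <- function(xSeries, kSeries, r) {
  n <- length(xSeries)
  if (n < 2L) stop("xSeries must have length >= 2")
  if (length(kSeries) == 1L) kSeries <- rep(kSeries, n)
  if (length(kSeries) != n) stop("kSeries must align with xSeries")
  if (any(!is.finite(xSeries)) || any(xSeries <= 0))
    stop("xSeries must be finite and strictly positive (zero biomass cannot be inverted)")
  t <- seq_len(n - 1L)
  a <- 1 + r * (1 - xSeries[t] / kSeries[t]) - xSeries[t + 1L] / xSeries[t]
  attr(a, "flagged") <- a < 0 | a > 1
  a
}

#' Standardise an assessed SSB series onto the model's 0-1 scale
#'
#' An assessment agency's SSB (in log10) is on an arbitrary scale; the
#' model needs dSSB strictly inside (0, min_t K_t) — below the carrying
#' capacity at every time, above full extirpation. Among all affine maps of
#' the log10 series that satisfy that constraint, the one chosen maximises
#' the Pearson correlation between the inversely-estimated fishing
#' intensity and the agency's independent fishing-effort series. The search
#' is a grid over the images (lo, hi) of the series range, refined once
#' around the optimum; ties break toward mid-range placement.
#'
#' @param logSsb log10 SSB per year
#' @param kSeries mdSSB per year (or a \linkS4class{CarryingCapacitySeries})
#' @param effort external fishing-effort series, aligned with
#'   \code{logSsb}; the first \code{n - 1} values are used (alpha estimates
#'   describe transitions)
#' @param r population growth rate
#' @param gridN grid resolution per axis (default 200)
#' @param refine refine once around the coarse optimum
#' @return a \linkS4class{StandardisationMap}; its \code{x} slot carries
#'   the mapped dSSB series
#' @export
standardiseSsb <- function(logSsb, kSeries, effort, r = 0.5, gridN = 200,
                           refine = TRUE) {
  if (is(kSeries, "CarryingCapacitySeries")) kSeries <- kSeries@values
  n <- length(logSsb)
  stopifnot(length(kSeries) == n, length(effort) >= n - 1L)
  if (!all(is.finite(logSsb))) stop("logSsb must be finite")
  rngL <- range(logSsb)
  if (diff(rngL) == 0) stop("logSsb series is constant; no feasible map")
  kMin <- min(kSeries)
  if (!is.finite(kMin) || kMin <= 0)
    stop("min(kSeries) must be > 0 for a feasible standardisation")
  f <- effort[seq_len(n - 1L)]
  if (stats::sd(f) == 0) stop("effort series has zero variance")

  evalMap <- function(lo, hi) {
    x <- lo + (logSsb - rngL[1]) / diff(rngL) * (hi - lo)
    a <- 1 + r * (1 - x[-n] / kSeries[-n]) - x[-1] / x[-n]
    if (stats::sd(a) == 0) return(NA_real_)
    stats::cor(a, f)
  }
  searchGrid <- function(loRange, hiRange) {
    los <- seq(loRange[1], loRange[2], length.out = gridN)
    his <- seq(hiRange[1], hiRange[2], length.out = gridN)
    best <- list(obj = -Inf, lo = NA, hi = NA)
    for (lo in los) {
      ok <- his > lo
      for (hi in his[ok]) {
        obj <- evalMap(lo, hi)
        if (is.na(obj)) next
        better <- obj > best$obj + 1e-12 ||
          (abs(obj - best$obj) <= 1e-12 &&
             abs((lo + hi) / 2 - kMin / 2) < abs((best$lo + best$hi) / 2 - kMin / 2))
        if (better) best <- list(obj = obj, lo = lo, hi = hi)
      }
    }
    best
  }
  eps <- kMin * 1e-3
  best <- searchGrid(c(eps, kMin - eps), c(eps, kMin - eps))
  if (!is.finite(best$obj)) {
    return(new("StandardisationMap", scale = NA_real_, offset = NA_real_,
               feasible = FALSE, objective = NA_real_, x = numeric(0)))
  }
  if (refine) {
    stepSz <- (kMin - 2 * eps) / (gridN - 1)
    loR <- pmin(pmax(c(best$lo - stepSz, best$lo + stepSz), eps), kMin - eps)
    hiR <- pmin(pmax(c(best$hi - stepSz, best$hi + stepSz), eps), kMin - eps)
    best2 <- searchGrid(loR, hiR)
    if (is.finite(best2$obj) && best2$obj >= best$obj) best <- best2
  }
  scale <- (best$hi - best$lo) / diff(rngL)
  offset <- best$lo - scale * rngL[1]
  new("StandardisationMap", scale = scale, offset = offset, feasible = TRUE,
      objective = best$obj, x = scale * logSsb + offset)
}

#' Reconstruct the observed trajectory and its four counterfactuals
#'
#' Runs the harvested logistic map (extirpation rule off — this is a
#' historical reconstruction) under the observed, time-varying forcing and
#' under four hypothetical scenarios that freeze one forcing at an observed
#' extreme: fishing intensity at its minimum or maximum with K varying
#' (environment-only variability), and K at its minimum or maximum with
#' fishing varying (fishing-only variability).
#'
#' @param x0 initial dSSB (the first observed value, by convention)
#' @param kSeries observed annual mdSSB
#' @param alphaSeries estimated annual fishing intensity (length n or n-1)
#' @param r population growth rate
#' @param years calendar years
#' @return a \linkS4class{CounterfactualSet}
#' @export
reconstructCounterfactuals <- function(x0, kSeries, alphaSeries, r = 0.5,
                                       years = seq_along(kSeries)) {
  cfg <- dynamicsConfig(extirpationRuleEnabled = FALSE)
  n <- length(kSeries)
  if (length(alphaSeries) == n - 1L) alphaSeries <- c(alphaSeries, alphaSeries[n - 1L])
  stopifnot(length(alphaSeries) == n)
  aMin <- min(alphaSeries); aMax <- max(alphaSeries)
  kMin <- min(kSeries); kMax <- max(kSeries)
  run <- function(kS, aS) simulateStock(x0, kS, aS, r, cfg, years)
  new("CounterfactualSet",
      full = run(kSeries, alphaSeries),
      alphaMinFixed = run(kSeries, rep(aMin, n)),
      alphaMaxFixed = run(kSeries, rep(aMax, n)),
      kMinFixed = run(rep(kMin, n), alphaSeries),
      kMaxFixed = run(rep(kMax, n), alphaSeries))
}

#' Per-year influence series of fishing and environment
#'
#' Residuals of the reconstructed trajectory against the mean of the two
#' constant-K counterfactuals (isolating what time-varying fishing did:
#' the fishing influence series) and against the mean of the two
#' constant-fishing counterfactuals (isolating what the changing
#' environment did). Signs are retained; in the reference analysis the
#' fishing series plots as a negative influence.
#'
#' @param set a \linkS4class{CounterfactualSet}
#' @return data.frame with columns \code{year}, \code{fishing},
#'   \code{environment}
#' @export
influenceSeries <- function(set) {
  stopifnot(is(set, "CounterfactualSet"))
  full <- set@full@x
  fishing <- full - (set@kMinFixed@x + set@kMaxFixed@x) / 2
  environment <- full - (set@alphaMinFixed@x + set@alphaMaxFixed@x) / 2
  data.frame(year = set@full@years, fishing = fishing,
             environment = environment)
}

attributionComponents <- function(set, idx, mapping) {
  full <- set@full@x[idx]
  if (mapping == "default") {
    gam <- mean(abs(full - set@alphaMinFixed@x[idx]))
    del <- mean(abs(full - set@kMaxFixed@x[idx]))
  } else {  # alternative reading of the component-to-curve mapping
    gam <- mean(abs(full - set@kMaxFixed@x[idx]))
    del <- mean(abs(full - set@alphaMinFixed@x[idx]))
  }
  c(gamma = gam, delta = del)
}

#' Fishing-influence index over a period
#'
#' Attribution of stock variability to fishing versus environment over a
#' period of years. The fishing component gamma is the mean absolute
#' departure of the reconstructed trajectory from the minimal-fishing
#' counterfactual (the loss attributable to fishing beyond the least
#' fishing observed); the environment component delta is the mean absolute
#' departure from the best-environment (maximum-K) counterfactual (the
#' loss attributable to environmental degradation relative to the best
#' regime observed). The fishing-influence percentage is
#' \deqn{\epsilon = 100 \gamma / (\gamma + \delta).}
#' The component-to-curve mapping admits a second reading; it is exposed
#' through \code{mapping = "swapped"}. A leave-one-year-out jackknife over
#' the period yields the reported mean and min-max range.
#'
#' @param set a \linkS4class{CounterfactualSet}
#' @param period length-2 year interval (inclusive); default whole series
#' @param mapping \code{"default"} or \code{"swapped"} component reading
#' @param jackknife compute the leave-one-out summary (period >= 3 years)
#' @return an \linkS4class{AttributionResult}
#' @export
influenceIndex <- function(set, period = range(set@full@years),
                           mapping = c("default", "swapped"),
                           jackknife = TRUE) {
  stopifnot(is(set, "CounterfactualSet"))
  mapping <- match.arg(mapping)
  yrs <- set@full@years
  idx <- which(yrs >= period[1] & yrs <= period[2])
  if (!length(idx)) stop("period lies outside the series")
  comp <- attributionComponents(set, idx, mapping)
  eps <- if (sum(comp) == 0) NaN else 100 * comp[["gamma"]] / sum(comp)
  jk <- c(mean = NA_real_, min = NA_real_, max = NA_real_)
  if (jackknife && length(idx) >= 3L) {
    jk <- jackknifeEpsilon(set, period, mapping)
  }
  new("AttributionResult", periodStart = as.integer(period[1]),
      periodEnd = as.integer(period[2]), gamma = comp[["gamma"]],
      delta = comp[["delta"]], epsilon = as.numeric(eps),
      jackknifeMean = jk[["mean"]], jackknifeMin = jk[["min"]],
      jackknifeMax = jk[["max"]])
}

#' Jackknife of the fishing-influence index
#'
#' Recomputes epsilon over a period leaving each year out once, returning
#' the mean, minimum and maximum of the leave-one-out values.
#'
#' @inheritParams influenceIndex
#' @return named numeric: \code{mean}, \code{min}, \code{max}
#' @export
jackknifeEpsilon <- function(set, period = range(set@full@years),
                             mapping = c("default", "swapped")) {
  mapping <- match.arg(mapping)
  yrs <- set@full@years
  idx <- which(yrs >= period[1] & yrs <= period[2])
  if (length(idx) < 3L) stop("jackknife needs a period of at least 3 years")
  reps <- vapply(seq_along(idx), function(i) {
    comp <- attributionComponents(set, idx[-i], mapping)
    if (sum(comp) == 0) NaN else 100 * comp[["gamma"]] / sum(comp)
  }, numeric(1))
  c(mean = mean(reps), min = min(reps), max = max(reps))
}

#' Segment years into regimes by clustering
#'
#' Years described by several standardised series are clustered with
#' average-linkage (UPGMA) agglomerative clustering on Euclidean
#' distances; cluster labels are then converted into contiguous periods by
#' splitting wherever a year's label differs from its predecessor's. Each
#' input series is min-max standardised to [0, 1] first so every variable
#' contributes equally.
#'
#' @param seriesMatrix numeric matrix, years in rows, series in columns
#' @param kGroups number of clusters to cut the dendrogram at (the
#'   reference analysis uses 7 periods)
#' @param years calendar years labelling the rows
#' @return data.frame with columns \code{start}, \code{end}, \code{cluster}
#' @export
identifyPeriods <- function(seriesMatrix, kGroups = 7,
                            years = seq_len(nrow(seriesMatrix))) {
  seriesMatrix <- as.matrix(seriesMatrix)
  n <- nrow(seriesMatrix)
  if (kGroups > n) stop("kGroups cannot exceed the number of years")
  std <- apply(seriesMatrix, 2L, minmaxStandardise)
  cl <- euclideanUpgma(std, k = kGroups)
  lab <- cl$labels
  breaks <- which(diff(lab) != 0)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  data.frame(start = years[starts], end = years[ends],
             cluster = lab[starts])
}
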