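#' Harvest policies for projections
#'
#' Three management policies drive the projection simulations: a constant
#' fishing intensity (fraction removed per year), a constant standardised
#' catch (fixed removal per year), and a dynamic MSY rule that adjusts
#' intensity each year to the current carrying capacity so the stock is
#' held at the biomass of maximum surplus production.
#'
#' @param alpha constant removal fraction (reference value 0.04)
#' @return a policy object consumed by \code{\link{projectCell}}
#' @export
policyConstantAlpha <- function(alpha = 0.04) {
  stopifnot(alpha >= 0, alpha <= 1)
  structure(list(type = "constAlpha", alpha = alpha), class = "fishclimPolicy")
}

#' @rdname policyConstantAlpha
#' @param catch constant standardised catch (reference value 0.03, the
#'   2008-2019 mean)
#' @export
policyConstantCatch <- function(catch = 0.03) {
  stopifnot(catch >= 0)
  structure(list(type = "constCatch", catch = catch), class = "fishclimPolicy")
}

#' @rdname policyConstantAlpha
#' @param fraction fraction of K_t defining the target biomass X_MSY
#'   (default 0.5, i.e. X_MSY = K/2)
#' @export
policyMSY <- function(fraction = 0.5) {
  if (!(fraction > 0 && fraction <= 1))
    stop("the MSY biomass fraction must lie in (0, 1]")
  structure(list(type = "msy", fraction = fraction), class = "fishclimPolicy")
}

#' @export
print.fishclimPolicy <- function(x, ...) {
  cat(switch(x$type,
    constAlpha = sprintf("policy: constant intensity alpha = %g\n", x$alpha),
    constCatch = sprintf("policy: constant catch = %g\n", x$catch),
    msy = sprintf("policy: dynamic MSY, X_MSY = %g K\n", x$fraction)))
  invisible(x)
}

#' Dynamic MSY fishing intensity
#'
#' The intensity that holds the stock at the target biomass
#' X_MSY = fraction * K_t under the logistic map:
#' \deqn{\alpha_{MSY,t} = r (1 - X_{MSY,t} / K_t).}
#' With the default fraction 1/2 this is r/2 for every cell and year — the
#' rule adapts the absolute target to the moving carrying capacity while
#' the removal fraction stays constant.
#'
#' @param k carrying capacity K_t (> 0), any shape
#' @param r population growth rate
#' @param fraction X_MSY as a fraction of K_t, in (0, 1]
#' @return intensity, same shape as \code{k}
#' @examples
#' msyAlpha(1, 0.5)  # 0.25
#' @export
msyAlpha <- function(k, r = 0.5, fraction = 0.5) {
  if (!(fraction > 0 && fraction <= 1))
    stop("fraction must lie in (0, 1]")
  if (any(k <= 0, na.rm = TRUE)) stop("k must be > 0")
  r * (1 - fraction) + 0 * k  # constant in k; keep shape
}

policyAlpha <- function(policy, kSeries, r) {
  switch(policy$type,
    constAlpha = rep(policy$alpha, length(kSeries)),
    msy = msyAlpha(kSeries, r, policy$fraction),
    stop("policy has no per-year intensity"))
}

initialState <- function(policy, k1, r, x0Rule) {
  x0 <- switch(x0Rule,
    equilibrium = {
      if (policy$type == "constCatch") {
        disc <- 1 - 4 * policy$catch / (r * k1)
        if (disc > 0) k1 * (1 + sqrt(disc)) / 2 else k1 / 2
      } else {
        a1 <- policyAlpha(policy, k1, r)[1]
        equilibriumDssb(k1, r, a1)
      }
    },
    halfK = k1 / 2,
    K = k1,
    stop("unknown x0Rule"))
  max(x0, 1e-9)  # simulateStock requires a positive start
}

#' Project one cell's stock under a management policy
#'
#' Runs the harvested logistic map forward under a projected
#' carrying-capacity series and a harvest policy, with the extirpation
#' rule on (threshold 0.1, absorbing). The initial state defaults to the
#' equilibrium under the first year's carrying capacity and the policy's
#' intensity; K/2 and K are available alternatives.
#'
#' @param kSeries projected annual mdSSB for the cell
#' @param policy a policy from \code{\link{policyConstantAlpha}},
#'   \code{\link{policyConstantCatch}} or \code{\link{policyMSY}}
#' @param r population growth rate
#' @param x0Rule \code{"equilibrium"} (default), \code{"halfK"} or
#'   \code{"K"}
#' @param config \linkS4class{DynamicsConfig}; extirpation on by default
#' @param years calendar years
#' @return a \linkS4class{StockTrajectory}
#' @export
projectCell <- function(kSeries, policy, r = 0.5,
                        x0Rule = c("equilibrium", "halfK", "K"),
                        config = dynamicsConfig(extirpationRuleEnabled = TRUE),
                        years = seq_along(kSeries)) {
  x0Rule <- match.arg(x0Rule)
  stopifnot(inherits(policy, "fishclimPolicy"))
  x0 <- initialState(policy, kSeries[1], r, x0Rule)
  if (policy$type == "constCatch") {
    simulateConstantCatch(x0, kSeries, policy$catch, r, config, years)
  } else {
    simulateStock(x0, kSeries, policyAlpha(policy, kSeries, r), r, config,
                  years)
  }
}

projectGrid <- function(kField, policy, r, x0Rule, config, fun) {
  stopifnot(is(kField, "CarryingCapacityField"), kField@timeUnit == "annual")
  nlat <- length(kField@lat); nlon <- length(kField@lon)
  years <- as.integer(kField@time)
  out <- matrix(NA_real_, nlat, nlon)
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    ks <- kField@k[i, j, ]
    if (any(is.na(ks)) || all(ks <= 0)) next
    ks <- pmax(ks, 1e-9)
    traj <- projectCell(ks, policy, r, x0Rule, config, years)
    out[i, j] <- fun(traj)
  }
  out
}

#' Per-cell extirpation year under a policy
#'
#' Projects every grid cell of an annual carrying-capacity field under a
#' harvest policy and maps the year in which the stock first reaches the
#' extirpation threshold (NA where it never does, or where K is missing).
#'
#' @param kField annual \linkS4class{CarryingCapacityField} of projected K
#' @inheritParams projectCell
#' @return matrix [lat, lon] of extirpation years (NA = never/undefined)
#' @export
extirpationYearMap <- function(kField, policy, r = 0.5,
                               x0Rule = "equilibrium",
                               config = dynamicsConfig(extirpationRuleEnabled = TRUE)) {
  projectGrid(kField, policy, r, x0Rule, config,
              function(traj) as.numeric(traj@extirpatedYear))
}

#' Per-cell pooled standardised catch under a policy
#'
#' Projects every cell and accumulates the standardised catch alpha_t X_t
#' over the projection horizon (zero after extirpation).
#'
#' @inheritParams extirpationYearMap
#' @return matrix [lat, lon] of pooled catch
#' @export
pooledCatchMap <- function(kField, policy, r = 0.5, x0Rule = "equilibrium",
                           config = dynamicsConfig(extirpationRuleEnabled = TRUE)) {
  projectGrid(kField, policy, r, x0Rule, config,
              function(traj) sum(traj@catch))
}

#' Compare two scenario maps
#'
#' Cell-wise comparison of two per-cell maps from competing scenarios
#' (different warming pathways or management policies) over a bounding
#' box. For extirpation-year maps the difference b - a in years is
#' reported (positive when scenario b extirpates later); cells that never
#' extirpate on either side are censored (excluded) by default, or imputed
#' at horizon + 1 with \code{censor = "horizon"}. For catch maps the
#' percentage reduction 100 (a - b) / a is reported.
#'
#' @param mapA,mapB matrices [lat, lon] from
#'   \code{\link{extirpationYearMap}} or \code{\link{pooledCatchMap}}
#' @param lat,lon cell-centre axes of the maps
#' @param bbox numeric(4) lat/lon bounding box (default North Sea)
#' @param type \code{"year"} or \code{"catch"}
#' @param censor for year maps: \code{"exclude"} non-extirpating cells or
#'   impute \code{"horizon"} + 1
#' @param horizon last projection year (needed for horizon imputation)
#' @return list with \code{differences} (vector over included box cells),
#'   \code{median} and the comparison \code{type}
#' @export
compareScenarios <- function(mapA, mapB, lat, lon, bbox = c(51, 62, -3, 9.5),
                             type = c("year", "catch"),
                             censor = c("exclude", "horizon"),
                             horizon = NULL) {
  type <- match.arg(type)
  censor <- match.arg(censor)
  if (!identical(dim(mapA), dim(mapB))) stop("maps are on different grids")
  ilat <- which(lat >= bbox[1] & lat <= bbox[2])
  ilon <- which(lon >= bbox[3] & lon <= bbox[4])
  if (!length(ilat) || !length(ilon)) stop("bounding box misses the grid")
  a <- mapA[ilat, ilon]; b <- mapB[ilat, ilon]
  if (type == "year") {
    if (censor == "horizon") {
      if (is.null(horizon)) stop("horizon imputation needs the horizon year")
      a[is.na(a)] <- horizon + 1
      b[is.na(b)] <- horizon + 1
    }
    d <- as.vector(b - a)
  } else {
    d <- as.vector(100 * (a - b) / a)
    d[!is.finite(d)] <- NA
  }
  d <- d[!is.na(d)]
  list(differences = d,
       median = if (length(d)) stats::median(d) else NA_real_,
       type = type)
}
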