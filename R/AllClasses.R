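#' @import methods
NULL

#' Niche parameters for the environmental suitability model
#'
#' Holds every constant of the three-dimensional environmental niche:
#' the asymmetric Gaussian thermal response (optimum \code{yOpt}, lower- and
#' upper-side standard deviations \code{t1}, \code{t2}, maximum \code{c}),
#' the trapezoidal bathymetric response (breakpoints \code{theta1..theta4},
#' depth in metres, positive down) and the trophic rule (chlorophyll
#' threshold \code{chlMin} in mg m-3 sustained for at least
#' \code{windowDays} consecutive days).
#'
#' Defaults are the North Sea cod parameterisation: optimum 5.4 degC with
#' standard deviations 5.7 (cold side) and 4 (warm side), bathymetric
#' trapezoid (0, 1e-4, 200, 600) m, chlorophyll threshold 0.05 mg m-3 over
#' a 15-day window, and unit maximum suitability.
#'
#' @slot yOpt thermal optimum (degC)
#' @slot t1 lower-side (cold) standard deviation (degC)
#' @slot t2 upper-side (warm) standard deviation (degC)
#' @slot c maximum suitability, the plateau of every response (0-1)
#' @slot theta1,theta2,theta3,theta4 trapezoid breakpoints (m, positive down)
#' @slot chlMin chlorophyll threshold (mg m-3)
#' @slot windowDays minimum run length of days at or above \code{chlMin}
#' @export
setClass("NicheParameters",
  representation(
    yOpt = "numeric", t1 = "numeric", t2 = "numeric", c = "numeric",
    theta1 = "numeric", theta2 = "numeric", theta3 = "numeric",
    theta4 = "numeric", chlMin = "numeric", windowDays = "numeric"
  ),
  prototype(
    yOpt = 5.4, t1 = 5.7, t2 = 4, c = 1,
    theta1 = 0, theta2 = 1e-4, theta3 = 200, theta4 = 600,
    chlMin = 0.05, windowDays = 15
  )
)

setValidity("NicheParameters", function(object) {
  msg <- character()
  if (!(object@t1 > 0)) msg <- c(msg, "t1 must be > 0")
  if (!(object@t2 > 0)) msg <- c(msg, "t2 must be > 0")
  if (!(object@c > 0 && object@c <= 1)) msg <- c(msg, "c must be in (0, 1]")
  th <- c(object@theta1, object@theta2, object@theta3, object@theta4)
  if (is.unsorted(th)) msg <- c(msg, "theta1 <= theta2 <= theta3 <= theta4 required")
  if (object@chlMin < 0) msg <- c(msg, "chlMin must be >= 0")
  if (object@windowDays < 1) msg <- c(msg, "windowDays must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct niche parameters
#'
#' @param yOpt,t1,t2,c thermal response: optimum, cold-side and warm-side
#'   standard deviations (degC), maximum suitability
#' @param theta1,theta2,theta3,theta4 bathymetric trapezoid breakpoints (m)
#' @param chlMin chlorophyll threshold (mg m-3)
#' @param windowDays minimum consecutive days at or above \code{chlMin}
#' @return a validated \linkS4class{NicheParameters} object
#' @examples
#' p <- nicheParameters()
#' thermalSuitability(5.4, p)  # 1 at the optimum
#' @export
nicheParameters <- function(yOpt = 5.4, t1 = 5.7, t2 = 4, c = 1,
                            theta1 = 0, theta2 = 1e-4, theta3 = 200,
                            theta4 = 600, chlMin = 0.05, windowDays = 15) {
  new("NicheParameters", yOpt = yOpt, t1 = t1, t2 = t2, c = c,
      theta1 = theta1, theta2 = theta2, theta3 = theta3, theta4 = theta4,
      chlMin = chlMin, windowDays = windowDays)
}

#' Gridded environmental fields driving the niche model
#'
#' Regular latitude/longitude grid (cell-centre registration) carrying sea
#' surface temperature (degC, monthly or daily), daily chlorophyll-a
#' concentration (mg m-3) and time-invariant bathymetry (m, positive down).
#' Missing values are \code{NA}; land may be encoded as negative depth.
#'
#' @slot lat,lon cell-centre axes (degrees), strictly monotonic increasing
#' @slot sst array [lat, lon, time] of temperature (degC)
#' @slot sstDates \code{Date} axis of \code{sst} (first day of month for
#'   monthly data)
#' @slot chl array [lat, lon, day] of chlorophyll (mg m-3)
#' @slot dates daily \code{Date} axis of \code{chl}
#' @slot depth matrix [lat, lon] of bathymetry (m, positive down)
#' @export
setClass("EnvironmentalFields",
  representation(
    lat = "numeric", lon = "numeric",
    sst = "array", sstDates = "Date",
    chl = "array", dates = "Date",
    depth = "matrix"
  )
)

setValidity("EnvironmentalFields", function(object) {
  msg <- character()
  nlat <- length(object@lat); nlon <- length(object@lon)
  if (nlat > 1 && any(diff(object@lat) <= 0)) msg <- c(msg, "lat must be strictly increasing")
  if (nlon > 1 && any(diff(object@lon) <= 0)) msg <- c(msg, "lon must be strictly increasing")
  if (!identical(dim(object@sst)[1:2], c(nlat, nlon)))
    msg <- c(msg, "sst grid does not match lat/lon axes")
  if (!identical(dim(object@chl)[1:2], c(nlat, nlon)))
    msg <- c(msg, "chl grid does not match lat/lon axes")
  if (!identical(dim(object@depth), c(nlat, nlon)))
    msg <- c(msg, "depth grid does not match lat/lon axes")
  if (dim(object@sst)[3] != length(object@sstDates))
    msg <- c(msg, "sst time dimension does not match sstDates")
  if (dim(object@chl)[3] != length(object@dates))
    msg <- c(msg, "chl time dimension does not match dates")
  if (any(object@chl < 0, na.rm = TRUE)) msg <- c(msg, "chl must be >= 0 where defined")
  if (length(msg)) msg else TRUE
})

#' Gridded carrying-capacity field
#'
#' Maximum standardised spawning stock biomass (mdSSB, the model's carrying
#' capacity K, dimensionless on 0-1) on the working grid, at daily or
#' annual resolution.
#'
#' @slot lat,lon cell-centre axes (degrees)
#' @slot k array [lat, lon, time] of mdSSB in [0, 1] (NA = missing)
#' @slot time for daily fields a numeric representation of \code{Date};
#'   for annual fields the calendar years
#' @slot timeUnit \code{"daily"} or \code{"annual"}
#' @export
setClass("CarryingCapacityField",
  representation(lat = "numeric", lon = "numeric", k = "array",
                 time = "numeric", timeUnit = "character")
)

setValidity("CarryingCapacityField", function(object) {
  msg <- character()
  if (!object@timeUnit %in% c("daily", "annual"))
    msg <- c(msg, "timeUnit must be 'daily' or 'annual'")
  if (!identical(dim(object@k)[1:2], c(length(object@lat), length(object@lon))))
    msg <- c(msg, "k grid does not match lat/lon axes")
  if (dim(object@k)[3] != length(object@time))
    msg <- c(msg, "k time dimension does not match time axis")
  rng <- range(object@k, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1 + 1e-12))
    msg <- c(msg, "k values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Regional annual carrying-capacity series
#'
#' Annual mean mdSSB over a bounding box (unweighted mean over cells whose
#' centres fall inside the closed box).
#'
#' @slot years contiguous calendar years
#' @slot values annual mdSSB K_t in [0, 1]
#' @slot bbox numeric(4): latMin, latMax, lonMin, lonMax (degrees), or NAs
#'   when the series did not come from a spatial aggregation
#' @export
setClass("CarryingCapacitySeries",
  representation(years = "integer", values = "numeric", bbox = "numeric")
)

setValidity("CarryingCapacitySeries", function(object) {
  msg <- character()
  if (length(object@years) != length(object@values))
    msg <- c(msg, "years and values must have the same length")
  if (length(object@years) > 1 && any(diff(object@years) != 1L))
    msg <- c(msg, "years must be contiguous")
  v <- object@values[!is.na(object@values)]
  if (length(v) && (min(v) < 0 || max(v) > 1 + 1e-12))
    msg <- c(msg, "values must lie in [0, 1]")
  if (length(object@bbox) != 4) msg <- c(msg, "bbox must be numeric(4)")
  if (length(msg)) msg else TRUE
})

#' Dynamics configuration
#'
#' Policy switches for the harvested logistic simulation: the extirpation
#' threshold (dSSB at or below which a projected stock is treated as locally
#' extinct and absorbed at zero), the collapse fraction (dSSB as a fraction
#' of mdSSB defining stock collapse) and negative-value clamping.
#'
#' @slot extirpationThreshold dSSB treated as extirpation (default 0.1)
#' @slot extirpationRuleEnabled apply the absorbing extirpation rule
#' @slot collapseFraction fraction of mdSSB defining collapse (default 0.1)
#' @slot clampNegative clamp negative intermediate dSSB at 0
#' @export
setClass("DynamicsConfig",
  representation(extirpationThreshold = "numeric",
                 extirpationRuleEnabled = "logical",
                 collapseFraction = "numeric",
                 clampNegative = "logical"),
  prototype(extirpationThreshold = 0.1, extirpationRuleEnabled = FALSE,
            collapseFraction = 0.1, clampNegative = TRUE)
)

setValidity("DynamicsConfig", function(object) {
  msg <- character()
  if (!(object@extirpationThreshold > 0 && object@extirpationThreshold < 1))
    msg <- c(msg, "extirpationThreshold must be in (0, 1)")
  if (!(object@collapseFraction > 0 && object@collapseFraction < 1))
    msg <- c(msg, "collapseFraction must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @param extirpationThreshold dSSB level treated as extirpation
#' @param extirpationRuleEnabled logical; apply the absorbing rule (default
#'   off for historical reconstruction, turn on for projections)
#' @param collapseFraction fraction of mdSSB defining collapse
#' @param clampNegative clamp negative intermediate dSSB at 0
#' @return a \linkS4class{DynamicsConfig}
#' @rdname DynamicsConfig-class
#' @export
dynamicsConfig <- function(extirpationThreshold = 0.1,
                           extirpationRuleEnabled = FALSE,
                           collapseFraction = 0.1,
                           clampNegative = TRUE) {
  new("DynamicsConfig", extirpationThreshold = extirpationThreshold,
      extirpationRuleEnabled = extirpationRuleEnabled,
      collapseFraction = collapseFraction, clampNegative = clampNegative)
}

#' Simulated stock trajectory
#'
#' Annual standardised spawning stock biomass X_t produced by the harvested
#' logistic map, together with the forcing it was run under. \code{catch}
#' records the standardised removal alpha_t * X_t booked on the pre-step
#' biomass of each year.
#'
#' @slot years calendar years
#' @slot x dSSB per year (>= 0; identically 0 after extirpation)
#' @slot k mdSSB forcing per year
#' @slot alpha fishing intensity per year (fraction of dSSB removed)
#' @slot catch standardised catch per year
#' @slot r population growth rate (per year)
#' @slot extirpatedYear first year the extirpation threshold was reached,
#'   or NA
#' @export
setClass("StockTrajectory",
  representation(years = "integer", x = "numeric", k = "numeric",
                 alpha = "numeric", catch = "numeric", r = "numeric",
                 extirpatedYear = "integer")
)

setValidity("StockTrajectory", function(object) {
  msg <- character()
  n <- length(object@years)
  if (length(object@x) != n || length(object@k) != n ||
      length(object@alpha) != n || length(object@catch) != n)
    msg <- c(msg, "years, x, k, alpha and catch must share one length")
  if (any(object@x < 0, na.rm = TRUE)) msg <- c(msg, "x must be >= 0")
  if (!is.na(object@extirpatedYear)) {
    after <- object@years > object@extirpatedYear
    if (any(object@x[after] != 0)) msg <- c(msg, "x must be 0 after extirpatedYear")
  }
  if (length(msg)) msg else TRUE
})

#' Standardisation of an assessed SSB series onto the model scale
#'
#' Affine map of log10 SSB onto the model's 0-1 dSSB scale, chosen so the
#' inversely-estimated fishing intensity correlates maximally with the
#' assessment agency's fishing effort, under the feasibility constraint
#' that the mapped series stays strictly inside (0, min_t K_t).
#'
#' @slot scale multiplier applied to log10 SSB
#' @slot offset additive shift
#' @slot feasible whether any feasible map existed
#' @slot objective Pearson correlation between estimated alpha and effort
#' @slot x the mapped dSSB series
#' @export
setClass("StandardisationMap",
  representation(scale = "numeric", offset = "numeric", feasible = "logical",
                 objective = "numeric", x = "numeric")
)

#' Counterfactual trajectory set
#'
#' The reconstructed trajectory under observed, time-varying fishing
#' intensity and carrying capacity ("full"), plus the four counterfactuals
#' holding one forcing constant at its observed extreme: lowest/highest
#' fishing intensity with varying K, and lowest/highest K with varying
#' fishing. All five share years, growth rate and initial state.
#'
#' @slot full,alphaMinFixed,alphaMaxFixed,kMinFixed,kMaxFixed
#'   \linkS4class{StockTrajectory} objects
#' @export
setClass("CounterfactualSet",
  representation(full = "StockTrajectory",
                 alphaMinFixed = "StockTrajectory",
                 alphaMaxFixed = "StockTrajectory",
                 kMinFixed = "StockTrajectory",
                 kMaxFixed = "StockTrajectory")
)

setValidity("CounterfactualSet", function(object) {
  yrs <- object@full@years
  for (s in c("alphaMinFixed", "alphaMaxFixed", "kMinFixed", "kMaxFixed")) {
    if (!identical(slot(object, s)@years, yrs))
      return("all trajectories must share the same years")
  }
  TRUE
})

#' Fishing-versus-environment attribution for one period
#'
#' The fishing component gamma (mean absolute departure of the
#' reconstructed trajectory from the minimal-fishing counterfactual), the
#' environment component delta (departure from the best-environment
#' counterfactual), the fishing-influence percentage
#' epsilon = 100 gamma / (gamma + delta), and its leave-one-year-out
#' jackknife summary.
#'
#' @slot periodStart,periodEnd year interval (inclusive)
#' @slot gamma,delta,epsilon attribution components; epsilon in [0, 100]
#'   (NaN when gamma + delta = 0)
#' @slot jackknifeMean,jackknifeMin,jackknifeMax leave-one-out epsilon
#' @export
setClass("AttributionResult",
  representation(periodStart = "integer", periodEnd = "integer",
                 gamma = "numeric", delta = "numeric", epsilon = "numeric",
                 jackknifeMean = "numeric", jackknifeMin = "numeric",
                 jackknifeMax = "numeric")
)

#' Sensitivity surfaces of equilibrium dSSB
#'
#' Equilibrium dSSB X(alpha, K) on a regular (fishing intensity, carrying
#' capacity) grid, the absolute central-difference sensitivities zeta
#' (along alpha) and eta (along K), their elementwise sum I and its min-max
#' standardisation I* in [0, 1]. Matrices are oriented [alpha, K].
#'
#' @slot alphaAxis,kAxis grid nodes
#' @slot xSurface,zeta,eta,iRaw,iStar matrices [alpha, K]
#' @slot r population growth rate used
#' @export
setClass("SensitivityGrids",
  representation(alphaAxis = "numeric", kAxis = "numeric",
                 xSurface = "matrix", zeta = "matrix", eta = "matrix",
                 iRaw = "matrix", iStar = "matrix", r = "numeric")
)
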