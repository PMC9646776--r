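#' Configuration for the synthetic-data generator
#'
#' Describes a deterministic synthetic study region and stock: a regular
#' grid with a meridional SST gradient, sinusoidal seasonality and a
#' linear warming trend; daily chlorophyll with a spring bloom of
#' configurable length above a sub-threshold background; a shelf
#' bathymetry profile spanning the trapezoidal response; and a harvested
#' stock driven by a known fishing-intensity schedule. The same seed gives
#' bit-identical outputs, so every downstream method can be tested against
#' known ground truth without any external ocean or assessment data.
#'
#' The defaults emulate a North-Sea-like shelf: 20 x 20 cells at 0.25
#' degrees from 51 N, 3 W; 60 years; SST around the thermal optimum with a
#' seasonal cycle of 4 degC and a +0.02 degC/yr trend; background
#' chlorophyll 0.04 mg m-3 (below the 0.05 threshold) with a 40-day spring
#' bloom at 0.30 mg m-3; depths from land (negative) across the shelf to
#' beyond 600 m; r = 0.5 and a rise-and-fall fishing schedule peaking at
#' 0.4.
#'
#' @param seed integer seed for every stochastic element
#' @param nLat,nLon grid size
#' @param resolution cell size (degrees)
#' @param latMin,lonMin grid origin (edges; centres sit half a cell in)
#' @param years calendar years covered
#' @param sst list: \code{base} (degC at the southern edge), \code{latGradient}
#'   (degC per degree latitude, negative = cooler northward),
#'   \code{seasonalAmplitude} (degC), \code{trendPerYear} (degC/yr)
#' @param chl list: \code{background}, \code{bloomValue} (mg m-3),
#'   \code{bloomStartDoy}, \code{bloomLength} (days)
#' @param depth list: \code{min}, \code{max} (m) across the longitude axis
#' @param stock list: \code{r}; \code{x0} (initial dSSB as a fraction of
#'   the minimum K, which keeps the synthetic truth strictly inside the
#'   feasible standardisation band); \code{alphaFloor}, \code{alphaPeak}
#'   (the rise-and-fall intensity schedule); \code{effortNoiseSd};
#'   \code{ssbScale}, \code{ssbOffset} (the affine disguise applied to the
#'   exported "log10 SSB")
#' @return a list of class \code{"FixtureConfig"}
#' @export
fixtureConfig <- function(seed = 1L, nLat = 20L, nLon = 20L,
                          resolution = 0.25, latMin = 51, lonMin = -3,
                          years = 1960:2019,
                          sst = list(base = 9, latGradient = -0.6,
                                     seasonalAmplitude = 4,
                                     trendPerYear = 0.02),
                          chl = list(background = 0.04, bloomValue = 0.30,
                                     bloomStartDoy = 91, bloomLength = 40),
                          depth = list(min = -50, max = 700),
                          stock = list(r = 0.5, x0 = 0.5, alphaFloor = 0.15,
                                       alphaPeak = 0.4, effortNoiseSd = 0,
                                       ssbScale = 2, ssbOffset = 3)) {
  if (nLat < 2L || nLon < 2L) stop("degenerate grid shape")
  structure(list(seed = as.integer(seed), nLat = as.integer(nLat),
                 nLon = as.integer(nLon), resolution = resolution,
                 latMin = latMin, lonMin = lonMin, years = years,
                 sst = sst, chl = chl, depth = depth, stock = stock),
            class = "FixtureConfig")
}

#' Generate synthetic environmental fields
#'
#' Builds the gridded SST (monthly), daily chlorophyll and bathymetry
#' described by a \code{\link{fixtureConfig}}. SST at cell (lat, lon) in
#' month m of year t is base + gradient * (lat - latMin) + seasonal cosine
#' peaking in August + trend * (t - firstYear). Chlorophyll is the
#' background everywhere except a bloom window of exactly
#' \code{bloomLength} days starting at \code{bloomStartDoy} each year.
#' Depth increases linearly across the longitude axis from \code{min}
#' (land when negative) to \code{max}, identical in every row.
#'
#' @param config a \code{\link{fixtureConfig}}
#' @return an \linkS4class{EnvironmentalFields}
#' @export
makeEnvironment <- function(config) {
  stopifnot(inherits(config, "FixtureConfig"))
  res <- config$resolution
  lat <- config$latMin + (seq_len(config$nLat) - 0.5) * res
  lon <- config$lonMin + (seq_len(config$nLon) - 0.5) * res
  yrs <- config$years
  ny <- length(yrs)

  # monthly SST
  sstDates <- as.Date(paste(rep(yrs, each = 12), rep(1:12, ny), 1, sep = "-"))
  months <- rep(1:12, ny)
  yearIdx <- rep(seq_len(ny) - 1L, each = 12)
  seasonal <- config$sst$seasonalAmplitude * cos(2 * pi * (months - 8) / 12)
  latTerm <- config$sst$latGradient * (lat - config$latMin)
  sst <- array(NA_real_, c(config$nLat, config$nLon, length(sstDates)))
  for (t in seq_along(sstDates)) {
    sst[, , t] <- config$sst$base + latTerm +
      seasonal[t] + config$sst$trendPerYear * yearIdx[t]
  }
  sst <- pmin(pmax(sst, -2), 35)

  # daily chlorophyll with an exact-length spring bloom
  dates <- seq(as.Date(paste0(yrs[1], "-01-01")),
               as.Date(paste0(yrs[ny], "-12-31")), by = "day")
  doy <- as.integer(format(dates, "%j"))
  bloom <- doy >= config$chl$bloomStartDoy &
    doy < config$chl$bloomStartDoy + config$chl$bloomLength
  chlDay <- ifelse(bloom, config$chl$bloomValue, config$chl$background)
  chl <- array(rep(chlDay, each = config$nLat * config$nLon),
               c(config$nLat, config$nLon, length(dates)))

  depthProfile <- seq(config$depth$min, config$depth$max,
                      length.out = config$nLon)
  depth <- matrix(rep(depthProfile, each = config$nLat),
                  config$nLat, config$nLon)

  new("EnvironmentalFields", lat = lat, lon = lon, sst = sst,
      sstDates = sstDates, chl = chl, dates = dates, depth = depth)
}

#' Generate a synthetic observed stock table with known truth
#'
#' Simulates the harvested logistic stock under a known rise-and-fall
#' fishing-intensity schedule forced by a carrying-capacity series, then
#' exports it the way an assessment agency would publish it: an
#' affine-disguised "log10 SSB" column, an effort column equal to the true
#' intensity plus optional observation noise, and a recruitment proxy.
#' The generating truth (true dSSB, true alpha, the disguise parameters)
#' is attached as attribute \code{"truth"} for assertions.
#'
#' @param config a \code{\link{fixtureConfig}}
#' @param kSeries a \linkS4class{CarryingCapacitySeries} or numeric vector
#'   of annual K aligned with \code{config$years}
#' @return data.frame with columns \code{year}, \code{ssb_log10},
#'   \code{recruitment_log10}, \code{effort_f}; attribute \code{truth}
#' @export
makeStockSeries <- function(config, kSeries) {
  stopifnot(inherits(config, "FixtureConfig"))
  if (is(kSeries, "CarryingCapacitySeries")) kSeries <- kSeries@values
  n <- length(config$years)
  if (length(kSeries) != n)
    stop("kSeries length is incompatible with the configured years")
  st <- config$stock
  # rise-and-fall intensity: moderate early, peak two-thirds through,
  # easing off. The floor keeps equilibria (and hence the whole truth
  # trajectory) strictly below min(K), so the exported series admits a
  # feasible standardisation back onto the model scale.
  tfrac <- seq(0, 1, length.out = n)
  alpha <- st$alphaFloor + (st$alphaPeak - st$alphaFloor) *
    exp(-((tfrac - 2 / 3) / 0.25)^2)
  x0 <- st$x0 * min(kSeries)
  traj <- simulateStock(x0, kSeries, alpha, st$r,
                        dynamicsConfig(extirpationRuleEnabled = FALSE),
                        years = config$years)
  x <- traj@x
  set.seed(config$seed)
  effort <- alpha + if (st$effortNoiseSd > 0)
    stats::rnorm(n, 0, st$effortNoiseSd) else 0
  recruitment <- log10(pmax(kSeries, 1e-6) * 1e5) +
    stats::rnorm(n, 0, 0.05)
  out <- data.frame(year = config$years,
                    ssb_log10 = st$ssbScale * x + st$ssbOffset,
                    recruitment_log10 = recruitment,
                    effort_f = effort)
  attr(out, "truth") <- list(x = x, alpha = alpha,
                             scale = st$ssbScale, offset = st$ssbOffset,
                             r = st$r)
  out
}
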