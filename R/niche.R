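#' Thermal suitability (asymmetric Gaussian response)
#'
#' Suitability of a temperature \code{y} under an asymmetric Gaussian
#' response with a common optimum and side-specific standard deviations:
#' \deqn{U_1(y) = c \exp(-(y - y_{opt})^2 / (2 t_1^2))} for \eqn{y \le
#' y_{opt}} and the same with \eqn{t_2} above the optimum. Non-finite
#' temperatures yield \code{NA} rather than an error so gridded fields with
#' gaps pass through.
#'
#' @param y temperature (degC), any shape
#' @param params \linkS4class{NicheParameters}
#' @return suitability in (0, c], same shape as \code{y}; NA where \code{y}
#'   is not finite
#' @examples
#' p <- nicheParameters()
#' thermalSuitability(c(5.4, 5.4 - 5.7, 5.4 + 4), p)  # c, exp(-1/2), exp(-1/2)
#' @export
thermalSuitability <- function(y, params = nicheParameters()) {
  validObject(params)
  sd <- ifelse(y <= params@yOpt, params@t1, params@t2)
  u <- params@c * exp(-(y - params@yOpt)^2 / (2 * sd^2))
  u[!is.finite(y)] <- NA_real_
  u
}

#' Bathymetric suitability (trapezoidal response)
#'
#' Trapezoidal membership along depth \code{z} (m, positive down): 0 at or
#' shallower than theta1 (including land encoded as negative depth), a
#' linear ramp up to theta2, the plateau \code{c} on (theta2, theta3), a
#' linear ramp down to theta4 and 0 at or beyond it. Zero-width ramps act
#' as step edges.
#'
#' @param z depth (m, positive down), any shape
#' @inheritParams thermalSuitability
#' @return suitability in [0, c]; NA where \code{z} is not finite
#' @export
bathymetricSuitability <- function(z, params = nicheParameters()) {
  validObject(params)
  t1 <- params@theta1; t2 <- params@theta2
  t3 <- params@theta3; t4 <- params@theta4
  u <- numeric(length(z))
  dim(u) <- dim(z)
  up <- z > t1 & z <= t2
  if (t2 > t1) u[up] <- (z[up] - t1) / (t2 - t1) * params@c else u[up] <- params@c
  u[z > t2 & z < t3] <- params@c
  down <- z >= t3 & z < t4
  if (t4 > t3) u[down] <- (t4 - z[down]) / (t4 - t3) * params@c else u[down] <- 0
  u[!is.finite(z)] <- NA_real_
  u
}

#' Trophic suitability (chlorophyll run-length rule)
#'
#' Binary daily suitability from a gap-free daily chlorophyll series: a day
#' scores 1 if and only if it belongs to a run of at least
#' \code{windowDays} consecutive days with chlorophyll at or above
#' \code{chlMin}. Days with missing chlorophyll break runs and propagate as
#' NA. The threshold comparison is \code{>=}: at exact equality measurement
#' precision dominates any strict/non-strict distinction.
#'
#' @param chlSeries daily chlorophyll (mg m-3), one cell
#' @inheritParams thermalSuitability
#' @return integer-valued vector of 0/1 (NA where input missing)
#' @export
trophicSuitability <- function(chlSeries, params = nicheParameters()) {
  validObject(params)
  n <- length(chlSeries)
  if (n < params@windowDays) {
    warning("series shorter than the run-length window; no day can qualify")
    out <- numeric(n)
    out[is.na(chlSeries)] <- NA_real_
    return(out)
  }
  above <- !is.na(chlSeries) & chlSeries >= params@chlMin
  r <- rle(above)
  qualifies <- r$values & r$lengths >= params@windowDays
  out <- as.numeric(inverse.rle(list(lengths = r$lengths, values = qualifies)))
  out[is.na(chlSeries)] <- NA_real_
  out
}

#' Combine suitability components multiplicatively
#'
#' The niche dimensions combine as a product, so a single unsuitable
#' dimension (component 0) forces combined suitability 0 — the
#' multiplicative nil rule. Missing components propagate as NA so data gaps
#' are not mistaken for unsuitability.
#'
#' @param ... suitability components in [0, 1], vectors or arrays of one
#'   common shape (or scalars, recycled)
#' @return elementwise product
#' @examples
#' combineSuitabilities(0.8, 0.5, 1)  # 0.4
#' @export
combineSuitabilities <- function(...) {
  comps <- list(...)
  if (length(comps) == 1L && is.list(comps[[1L]])) comps <- comps[[1L]]
  if (length(comps) == 0L) stop("at least one suitability component is required")
  Reduce(`*`, comps)
}

# Expand an SST field stored at its own (e.g. monthly) time axis onto daily
# dates. "constant" holds each step's value over the days it covers;
# "linear" interpolates in time between step midpoints.
broadcastSst <- function(sst, sstDates, dates, method = c("constant", "linear")) {
  method <- match.arg(method)
  nlat <- dim(sst)[1]; nlon <- dim(sst)[2]
  ts <- as.numeric(sstDates); td <- as.numeric(dates)
  out <- array(NA_real_, c(nlat, nlon, length(dates)))
  if (method == "constant") {
    idx <- findInterval(td, ts)
    idx[idx < 1L] <- 1L
    out <- sst[, , idx, drop = FALSE]
  } else {
    flat <- matrix(sst, nrow = nlat * nlon)
    res <- t(apply(flat, 1L, function(v) {
      if (all(is.na(v))) return(rep(NA_real_, length(td)))
      stats::approx(ts, v, xout = td, rule = 2)$y
    }))
    out <- array(res, c(nlat, nlon, length(dates)))
  }
  out
}

#' Daily carrying-capacity field from environmental forcing
#'
#' Per cell and day, the carrying capacity (maximum standardised SSB) is
#' the product of the thermal, bathymetric and trophic suitabilities
#' evaluated on the environmental fields. SST supplied at a coarser (e.g.
#' monthly) resolution is broadcast to days, either held constant within
#' each step or linearly interpolated in time. Any missing component makes
#' that day's K missing.
#'
#' @param env \linkS4class{EnvironmentalFields}
#' @param params \linkS4class{NicheParameters}
#' @param sstMethod \code{"constant"} (default) or \code{"linear"} temporal
#'   broadcast of SST onto days
#' @return a daily \linkS4class{CarryingCapacityField}
#' @export
mdssbDaily <- function(env, params = nicheParameters(),
                       sstMethod = c("constant", "linear")) {
  validObject(env)
  sstMethod <- match.arg(sstMethod)
  sstDaily <- broadcastSst(env@sst, env@sstDates, env@dates, sstMethod)
  u1 <- thermalSuitability(sstDaily, params)
  u2 <- bathymetricSuitability(env@depth, params)
  nday <- length(env@dates)
  u3 <- env@chl
  # run-length rule per cell along the day axis
  for (i in seq_along(env@lat)) for (j in seq_along(env@lon)) {
    u3[i, j, ] <- suppressWarnings(trophicSuitability(env@chl[i, j, ], params))
  }
  k <- u1 * as.vector(u2) * u3  # u2 recycles over the day dimension
  new("CarryingCapacityField", lat = env@lat, lon = env@lon, k = k,
      time = as.numeric(env@dates), timeUnit = "daily")
}

#' Annual mean of a daily carrying-capacity field
#'
#' Averages daily K over the productive season of each year (March-October
#' by default), per cell. Cell-years with no valid day are missing.
#'
#' @param field a daily \linkS4class{CarryingCapacityField}
#' @param months integer months to average over (default 3:10)
#' @return an annual \linkS4class{CarryingCapacityField}
#' @export
annualizeK <- function(field, months = 3:10) {
  stopifnot(is(field, "CarryingCapacityField"), field@timeUnit == "daily")
  dates <- as.Date(field@time, origin = "1970-01-01")
  mo <- as.integer(format(dates, "%m"))
  yr <- as.integer(format(dates, "%Y"))
  sel <- mo %in% months
  if (!any(sel)) stop("no days fall inside the selected months")
  yrs <- sort(unique(yr[sel]))
  nlat <- length(field@lat); nlon <- length(field@lon)
  out <- array(NA_real_, c(nlat, nlon, length(yrs)))
  for (t in seq_along(yrs)) {
    idx <- which(sel & yr == yrs[t])
    sl <- field@k[, , idx, drop = FALSE]
    m <- rowMeans(matrix(sl, nrow = nlat * nlon), na.rm = TRUE)
    m[is.nan(m)] <- NA_real_  # cell-years with no valid day
    out[, , t] <- m
  }
  new("CarryingCapacityField", lat = field@lat, lon = field@lon, k = out,
      time = as.numeric(yrs), timeUnit = "annual")
}

#' Regional annual carrying-capacity series
#'
#' Unweighted mean of annual K over grid cells whose centres fall inside
#' the closed bounding box, one value per year. The North Sea box of the
#' reference analysis is 51-62 N, 3 W-9.5 E.
#'
#' @param field an annual \linkS4class{CarryingCapacityField}
#' @param bbox numeric(4): latMin, latMax, lonMin, lonMax (degrees)
#' @return a \linkS4class{CarryingCapacitySeries}
#' @export
regionalSeries <- function(field, bbox = c(51, 62, -3, 9.5)) {
  stopifnot(is(field, "CarryingCapacityField"), field@timeUnit == "annual")
  ilat <- which(field@lat >= bbox[1] & field@lat <= bbox[2])
  ilon <- which(field@lon >= bbox[3] & field@lon <= bbox[4])
  if (!length(ilat) || !length(ilon))
    stop("bounding box does not intersect the grid")
  vals <- vapply(seq_along(field@time), function(t) {
    sl <- field@k[ilat, ilon, t]
    if (all(is.na(sl))) NA_real_ else mean(sl, na.rm = TRUE)
  }, numeric(1))
  new("CarryingCapacitySeries", years = as.integer(field@time),
      values = vals, bbox = as.numeric(bbox))
}

#' Temporal climatology of an annual carrying-capacity field
#'
#' Per-cell mean of annual K over a year range, for mapping long-term mean
#' habitat suitability. The count of contributing years per cell is
#' attached as attribute \code{"nYears"}.
#'
#' @param field an annual \linkS4class{CarryingCapacityField}
#' @param yearRange length-2 integer range (inclusive); default all years
#' @return matrix [lat, lon] of mean K with attribute \code{nYears}
#' @export
climatologyMap <- function(field, yearRange = range(field@time)) {
  stopifnot(is(field, "CarryingCapacityField"), field@timeUnit == "annual")
  idx <- which(field@time >= yearRange[1] & field@time <= yearRange[2])
  if (!length(idx)) stop("year range selects no years")
  sl <- field@k[, , idx, drop = FALSE]
  nlat <- length(field@lat); nlon <- length(field@lon)
  flat <- matrix(sl, nrow = nlat * nlon)
  m <- matrix(rowMeans(flat, na.rm = TRUE), nlat, nlon)
  m[is.nan(m)] <- NA_real_
  attr(m, "nYears") <- matrix(rowSums(!is.na(flat)), nlat, nlon)
  m
}
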