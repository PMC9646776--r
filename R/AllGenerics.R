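# Accessor generics. Slot access from user code should go through these.

#' @rdname accessors
#' @param object an object from this package
#' @export
setGeneric("years", function(object) standardGeneric("years"))

#' @rdname accessors
#' @export
setGeneric("dssb", function(object) standardGeneric("dssb"))

#' @rdname accessors
#' @export
setGeneric("mdssb", function(object) standardGeneric("mdssb"))

#' @rdname accessors
#' @export
setGeneric("fishingIntensity", function(object) standardGeneric("fishingIntensity"))

#' @rdname accessors
#' @export
setGeneric("growthRate", function(object) standardGeneric("growthRate"))

#' @rdname accessors
#' @export
setGeneric("extirpatedYear", function(object) standardGeneric("extirpatedYear"))

#' @rdname accessors
#' @export
setGeneric("stdCatch", function(object) standardGeneric("stdCatch"))

#' @rdname accessors
#' @export
setGeneric("epsilon", function(object) standardGeneric("epsilon"))

#' Accessors for fishclim objects
#'
#' \code{years} returns the calendar-year axis; \code{dssb} the standardised
#' SSB series X_t; \code{mdssb} the carrying-capacity series K_t;
#' \code{fishingIntensity} the per-year intensity alpha_t; \code{stdCatch}
#' the standardised catch alpha_t X_t; \code{growthRate} the population
#' growth rate r; \code{extirpatedYear} the absorbing extirpation year (NA
#' if never reached); \code{epsilon} the fishing-influence percentage.
#'
#' @name accessors
#' @return the corresponding slot content, as a plain vector or scalar
NULL

#' @rdname accessors
setMethod("years", "StockTrajectory", function(object) object@years)
#' @rdname accessors
setMethod("years", "CarryingCapacitySeries", function(object) object@years)
#' @rdname accessors
setMethod("dssb", "StockTrajectory", function(object) object@x)
#' @rdname accessors
setMethod("dssb", "StandardisationMap", function(object) object@x)
#' @rdname accessors
setMethod("mdssb", "StockTrajectory", function(object) object@k)
#' @rdname accessors
setMethod("mdssb", "CarryingCapacitySeries", function(object) object@values)
#' @rdname accessors
setMethod("fishingIntensity", "StockTrajectory", function(object) object@alpha)
#' @rdname accessors
setMethod("growthRate", "StockTrajectory", function(object) object@r)
#' @rdname accessors
setMethod("extirpatedYear", "StockTrajectory", function(object) object@extirpatedYear)
#' @rdname accessors
setMethod("stdCatch", "StockTrajectory", function(object) object@catch)
#' @rdname accessors
setMethod("epsilon", "AttributionResult", function(object) object@epsilon)

setMethod("show", "NicheParameters", function(object) {
  cat("NicheParameters\n")
  cat(sprintf("  thermal: yOpt = %g degC, t1 = %g, t2 = %g, c = %g\n",
              object@yOpt, object@t1, object@t2, object@c))
  cat(sprintf("  bathymetric: theta = (%g, %g, %g, %g) m\n",
              object@theta1, object@theta2, object@theta3, object@theta4))
  cat(sprintf("  trophic: chl >= %g mg m-3 for >= %g days\n",
              object@chlMin, object@windowDays))
})

setMethod("show", "EnvironmentalFields", function(object) {
  cat("EnvironmentalFields\n")
  cat(sprintf("  grid: %d x %d cells, lat [%g, %g], lon [%g, %g]\n",
              length(object@lat), length(object@lon),
              min(object@lat), max(object@lat),
              min(object@lon), max(object@lon)))
  cat(sprintf("  sst: %d steps (%s .. %s)\n", length(object@sstDates),
              min(object@sstDates), max(object@sstDates)))
  cat(sprintf("  chl: %d days (%s .. %s)\n", length(object@dates),
              min(object@dates), max(object@dates)))
})

setMethod("show", "CarryingCapacityField", function(object) {
  cat(sprintf("CarryingCapacityField (%s): %d x %d cells, %d time steps\n",
              object@timeUnit, length(object@lat), length(object@lon),
              length(object@time)))
})

setMethod("show", "CarryingCapacitySeries", function(object) {
  cat(sprintf("CarryingCapacitySeries: %d years (%d-%d)",
              length(object@years), min(object@years), max(object@years)))
  if (all(is.finite(object@bbox)))
    cat(sprintf(", bbox %g-%gN %g-%gE", object@bbox[1], object@bbox[2],
                object@bbox[3], object@bbox[4]))
  cat(sprintf("\n  mean K = %.3f, range [%.3f, %.3f]\n",
              mean(object@values, na.rm = TRUE),
              min(object@values, na.rm = TRUE),
              max(object@values, na.rm = TRUE)))
})

setMethod("show", "StockTrajectory", function(object) {
  cat(sprintf("StockTrajectory: %d years (%d-%d), r = %g\n",
              length(object@years), min(object@years), max(object@years),
              object@r))
  cat(sprintf("  final dSSB = %.4f", object@x[length(object@x)]))
  if (!is.na(object@extirpatedYear))
    cat(sprintf(" (extirpated in %d)", object@extirpatedYear))
  cat("\n")
})

setMethod("show", "StandardisationMap", function(object) {
  cat(sprintf("StandardisationMap: x = %.4g * log10(SSB) + %.4g\n",
              object@scale, object@offset))
  cat(sprintf("  feasible = %s, corr(alpha_hat, F) = %.4f\n",
              object@feasible, object@objective))
})

setMethod("show", "CounterfactualSet", function(object) {
  yrs <- object@full@years
  cat(sprintf("CounterfactualSet: %d-%d, r = %g\n", min(yrs), max(yrs),
              object@full@r))
  cat(sprintf("  alpha range [%.3f, %.3f], K range [%.3f, %.3f]\n",
              min(object@full@alpha), max(object@full@alpha),
              min(object@full@k), max(object@full@k)))
})

setMethod("show", "AttributionResult", function(object) {
  cat(sprintf("AttributionResult %d-%d: epsilon = %.1f%% fishing",
              object@periodStart, object@periodEnd, object@epsilon))
  cat(sprintf(" (jackknife %.1f [%.1f, %.1f])\n", object@jackknifeMean,
              object@jackknifeMin, object@jackknifeMax))
})

setMethod("show", "SensitivityGrids", function(object) {
  cat(sprintf("SensitivityGrids: %d alpha x %d K nodes, r = %g; I* in [%.3f, %.3f]\n",
              length(object@alphaAxis), length(object@kAxis), object@r,
              min(object@iStar), max(object@iStar)))
})
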