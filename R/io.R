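#' Read an assessed stock table
#'
#' Reads the CSV stock dialect: one header row with a \code{year} column
#' plus named series columns (typically \code{ssb_log10},
#' \code{recruitment_log10}, \code{effort_f}). Years must be unique and
#' contiguous; unknown extra columns are preserved with a warning.
#'
#' @param path CSV file path
#' @return data.frame with an integer \code{year} column, years ascending
#' @export
readStockTable <- function(path) {
  tab <- utils::read.csv(path, check.names = TRUE)
  if (!"year" %in% names(tab)) stop("stock table must have a 'year' column")
  tab$year <- as.integer(tab$year)
  tab <- tab[order(tab$year), , drop = FALSE]
  dup <- tab$year[duplicated(tab$year)]
  if (length(dup)) stop("duplicate years: ", paste(dup, collapse = ", "))
  gaps <- setdiff(seq(min(tab$year), max(tab$year)), tab$year)
  if (length(gaps)) stop("missing years: ", paste(gaps, collapse = ", "))
  known <- c("year", "ssb_log10", "recruitment_log10", "effort_f")
  extra <- setdiff(names(tab), known)
  if (length(extra))
    warning("preserving unknown columns: ", paste(extra, collapse = ", "))
  rownames(tab) <- NULL
  tab
}

#' Write / read a regional carrying-capacity series
#'
#' Two-column CSV dialect (\code{year}, \code{k}); the bounding box is
#' carried in comment-free attribute columns is not — the box is stored in
#' a header comment line starting with \code{#bbox}.
#'
#' @param series a \linkS4class{CarryingCapacitySeries}
#' @param path file path
#' @return \code{readRegionalSeries} returns a
#'   \linkS4class{CarryingCapacitySeries}
#' @export
writeRegionalSeries <- function(series, path) {
  stopifnot(is(series, "CarryingCapacitySeries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#bbox %s", paste(series@bbox, collapse = ",")), con)
  utils::write.csv(data.frame(year = series@years, k = series@values),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRegionalSeries
#' @export
readRegionalSeries <- function(path) {
  first <- readLines(path, n = 1L)
  bbox <- rep(NA_real_, 4)
  skip <- 0L
  if (startsWith(first, "#bbox")) {
    bbox <- as.numeric(strsplit(sub("^#bbox ", "", first), ",")[[1]])
    skip <- 1L
  }
  tab <- utils::read.csv(path, skip = skip)
  new("CarryingCapacitySeries", years = as.integer(tab$year),
      values = tab$k, bbox = bbox)
}

#' Write / read a gridded field as long-format CSV
#'
#' Plain-text grid dialect: columns \code{lat}, \code{lon}, \code{time},
#' \code{value}, cell-centre registration, one row per cell and time step.
#' \code{readGridCsv} validates monotone axes and applies boundary unit
#' conventions: temperatures that look like kelvin (values above 200) are
#' converted to degC, chlorophyll in kg m-3 (the climate-model convention;
#' values below 1e-3) is converted to mg m-3, and longitudes on 0..360 are
#' rewrapped to -180..180.
#'
#' @param lat,lon cell-centre axes
#' @param time time axis (numeric; Date is stored as numeric days)
#' @param values array [lat, lon, time]
#' @param path file path
#' @param variable one of \code{"generic"}, \code{"sst"}, \code{"chl"}
#'   controlling unit normalisation on read
#' @return \code{readGridCsv} returns a list with \code{lat}, \code{lon},
#'   \code{time}, \code{values}
#' @export
writeGridCsv <- function(lat, lon, time, values, path) {
  stopifnot(identical(dim(values), c(length(lat), length(lon), length(time))))
  grid <- expand.grid(lat = lat, lon = lon, time = as.numeric(time))
  grid$value <- as.vector(values)
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGridCsv
#' @export
readGridCsv <- function(path, variable = c("generic", "sst", "chl")) {
  variable <- match.arg(variable)
  tab <- utils::read.csv(path)
  need <- c("lat", "lon", "time", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("grid file lacks column(s): ", paste(miss, collapse = ", "))
  if (max(tab$lon, na.rm = TRUE) > 180) {
    tab$lon <- ifelse(tab$lon > 180, tab$lon - 360, tab$lon)
    message("longitudes rewrapped from 0..360 to -180..180")
  }
  lat <- sort(unique(tab$lat)); lon <- sort(unique(tab$lon))
  time <- sort(unique(tab$time))
  if (length(lat) > 1 && any(diff(lat) <= 0)) stop("latitude axis not monotone")
  vals <- array(NA_real_, c(length(lat), length(lon), length(time)))
  idx <- cbind(match(tab$lat, lat), match(tab$lon, lon), match(tab$time, time))
  vals[idx] <- tab$value
  if (variable == "sst" && any(vals > 200, na.rm = TRUE)) {
    vals <- vals - 273.15
    message("SST read in kelvin; converted to degC")
  }
  if (variable == "chl" && all(vals < 1e-3, na.rm = TRUE)) {
    vals <- vals * 1e6
    message("chlorophyll read in kg m-3; converted to mg m-3")
  }
  list(lat = lat, lon = lon, time = time, values = vals)
}

#' Write a stock trajectory as CSV
#'
#' Columns: \code{year}, \code{k}, \code{alpha}, \code{x},
#' \code{extirpated} (0/1).
#'
#' @param traj a \linkS4class{StockTrajectory}
#' @param path file path
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(is(traj, "StockTrajectory"))
  ext <- if (is.na(traj@extirpatedYear)) rep(0L, length(traj@years))
         else as.integer(traj@years >= traj@extirpatedYear)
  utils::write.csv(data.frame(year = traj@years, k = traj@k,
                              alpha = traj@alpha, x = traj@x,
                              extirpated = ext),
                   path, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-data analysis pipeline
#'
#' End-to-end orchestration on generated data: build the environmental
#' fields, derive the daily and annual carrying capacity and its regional
#' series, generate an observed stock, standardise it back onto the model
#' scale, estimate fishing intensity, reconstruct the counterfactual set,
#' segment the years into regimes, attribute variability per period, and
#' compute the recovery-time table and a small scenario comparison. All
#' randomness derives from the config seed; rerunning with an identical
#' config reproduces the summary exactly.
#'
#' @param config a \code{\link{fixtureConfig}}
#' @param periods number of regimes for the year clustering
#' @param outDir optional directory; when given, CSV artefacts are written
#' @return a list: \code{kSeries}, \code{standardisation}, \code{alpha},
#'   \code{counterfactuals}, \code{periods}, \code{attribution} (one
#'   \linkS4class{AttributionResult} per period plus the whole range),
#'   \code{recoveryTable}, \code{scenarioMedians}
#' @export
runAnalysis <- function(config = fixtureConfig(), periods = 4,
                        outDir = NULL) {
  env <- makeEnvironment(config)
  kDaily <- mdssbDaily(env)
  kAnnual <- annualizeK(kDaily)
  bbox <- c(min(env@lat), max(env@lat), min(env@lon), max(env@lon))
  kSeries <- regionalSeries(kAnnual, bbox)

  stock <- makeStockSeries(config, kSeries)
  r <- config$stock$r
  std <- standardiseSsb(stock$ssb_log10, kSeries@values, stock$effort_f,
                        r = r, gridN = 80)
  alphaHat <- estimateAlpha(std@x, kSeries@values, r)
  cf <- reconstructCounterfactuals(std@x[1], kSeries@values, alphaHat, r,
                                   years = stock$year)
  infl <- influenceSeries(cf)
  mat <- cbind(dssb = cf@full@x, fishing = infl$fishing,
               environment = infl$environment)
  per <- identifyPeriods(mat, kGroups = periods, years = stock$year)
  attribution <- lapply(seq_len(nrow(per)), function(i) {
    influenceIndex(cf, c(per$start[i], per$end[i]))
  })
  attribution$whole <- influenceIndex(cf)

  recoveryTable <- expand.grid(r = c(0.25, 0.5, 0.75), k = c(1, 0.401))
  recoveryTable$years <- round(mapply(recoveryTime, recoveryTable$k,
                                      recoveryTable$r), 1)

  # small paired projection: constant intensity vs dynamic MSY on the
  # annual K field, over the fixture's years
  extConst <- extirpationYearMap(kAnnual, policyConstantAlpha(0.04), r)
  extMsy <- extirpationYearMap(kAnnual, policyMSY(), r)
  catchConst <- pooledCatchMap(kAnnual, policyConstantAlpha(0.04), r)
  catchMsy <- pooledCatchMap(kAnnual, policyMSY(), r)
  cmpYear <- compareScenarios(extConst, extMsy, env@lat, env@lon, bbox,
                              type = "year")
  cmpCatch <- compareScenarios(catchConst, catchMsy, env@lat, env@lon,
                               bbox, type = "catch")

  res <- list(kSeries = kSeries, standardisation = std, alpha = alphaHat,
              counterfactuals = cf, periods = per,
              attribution = attribution, recoveryTable = recoveryTable,
              scenarioMedians = list(extirpationYear = cmpYear$median,
                                     catchReduction = cmpCatch$median))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeRegionalSeries(kSeries, file.path(outDir, "k_series.csv"))
    writeTrajectory(cf@full, file.path(outDir, "reconstruction.csv"))
    att <- do.call(rbind, lapply(attribution, function(a) {
      data.frame(period_start = a@periodStart, period_end = a@periodEnd,
                 epsilon_mean = a@jackknifeMean, epsilon_min = a@jackknifeMin,
                 epsilon_max = a@jackknifeMax, epsilon = a@epsilon)
    }))
    utils::write.csv(att, file.path(outDir, "attribution.csv"),
                     row.names = FALSE)
    utils::write.csv(recoveryTable, file.path(outDir, "recovery.csv"),
                     row.names = FALSE)
  }
  res
}
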