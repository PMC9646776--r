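# Small grids/series shared across tests. Kept tiny so the suite runs in
# seconds; the generator's scientific defaults live in fixtureConfig().

smallConfig <- function(seed = 1L, years = 1990:1999, ...) {
  fixtureConfig(seed = seed, nLat = 6L, nLon = 6L, years = years, ...)
}

# Hand-built one-cell environment: constant SST, fixed depth, a single
# chlorophyll bloom of bloomDays days each year.
oneCellEnv <- function(sstValue = 5.4, depthValue = 100, years = 2000,
                       bloomDays = 20, bloomStart = 91,
                       background = 0.04, bloomValue = 0.06) {
  dates <- seq(as.Date(paste0(min(years), "-01-01")),
               as.Date(paste0(max(years), "-12-31")), by = "day")
  doy <- as.integer(format(dates, "%j"))
  chlDay <- ifelse(doy >= bloomStart & doy < bloomStart + bloomDays,
                   bloomValue, background)
  sstDates <- seq(as.Date(paste0(min(years), "-01-01")),
                  as.Date(paste0(max(years), "-12-01")), by = "month")
  lat <- c(54.125, 54.375); lon <- c(2.125, 2.375)
  nd <- length(dates); nm <- length(sstDates)
  new("EnvironmentalFields",
      lat = lat, lon = lon,
      sst = array(sstValue, c(2, 2, nm)), sstDates = sstDates,
      chl = array(rep(chlDay, each = 4), c(2, 2, nd)), dates = dates,
      depth = matrix(depthValue, 2, 2))
}
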