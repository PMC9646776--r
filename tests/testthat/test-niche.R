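test_that("thermal suitability matches the asymmetric Gaussian closed form", {
  p <- nicheParameters()
  expect_equal(thermalSuitability(5.4, p), 1)           # value at the optimum is c
  expect_equal(thermalSuitability(5.4 - 5.7, p), exp(-0.5))  # one sigma, cold side
  expect_equal(thermalSuitability(5.4 + 4, p), exp(-0.5))    # one sigma, warm side
  expect_equal(thermalSuitability(20, p), exp(-14.6^2 / 32))
  # non-finite input flags missing instead of erroring on a grid
  expect_true(is.na(thermalSuitability(NA_real_, p)))
  expect_true(is.na(thermalSuitability(Inf, p)))
})

test_that("thermal suitability is maximal at the optimum and decreases away from it", {
  p <- nicheParameters()
  yLow <- sort(runif(50, -10, p@yOpt))
  yHigh <- sort(runif(50, p@yOpt, 25))
  expect_true(all(diff(thermalSuitability(yLow, p)) > 0))
  expect_true(all(diff(thermalSuitability(yHigh, p)) < 0))
  expect_true(all(thermalSuitability(runif(200, -5, 30), p) <= p@c))
})

test_that("bathymetric suitability follows the trapezoid", {
  p <- nicheParameters()
  expect_equal(bathymetricSuitability(100, p), 1)    # plateau
  expect_equal(bathymetricSuitability(400, p), 0.5)  # descending ramp midpoint
  expect_equal(bathymetricSuitability(650, p), 0)    # beyond theta4
  expect_equal(bathymetricSuitability(5e-5, p), 0.5) # ascending ramp midpoint
  expect_equal(bathymetricSuitability(-10, p), 0)    # land: negative depth
  expect_equal(bathymetricSuitability(0, p), 0)      # z <= theta1 branch
  # zero-width ascending ramp behaves as a step edge
  pStep <- nicheParameters(theta1 = 0, theta2 = 0, theta3 = 200, theta4 = 600)
  expect_equal(bathymetricSuitability(1e-9, pStep), 1)
  expect_equal(bathymetricSuitability(-1e-9, pStep), 0)
})

test_that("trophic suitability scores membership in qualifying runs only", {
  p <- nicheParameters()
  chl <- rep(0.04, 365)
  chl[101:120] <- 0.06  # 20-day run above threshold
  u <- trophicSuitability(chl, p)
  expect_equal(which(u == 1), 101:120)
  expect_true(all(u[-(101:120)] == 0))

  expect_true(all(trophicSuitability(rep(0.04, 100), p) == 0))

  chl14 <- rep(0.01, 60); chl14[10:23] <- 0.10  # run of exactly 14 days
  expect_true(all(trophicSuitability(chl14, p) == 0))

  # threshold comparison is >=
  expect_true(all(trophicSuitability(rep(0.05, 30), p) == 1))
  # short series cannot qualify and warns
  expect_warning(u0 <- trophicSuitability(rep(0.5, 10), p), "shorter")
  expect_true(all(u0 == 0))
  # missing days break runs and propagate
  chlNA <- rep(0.06, 40); chlNA[20] <- NA
  uNA <- trophicSuitability(chlNA, p)
  expect_true(is.na(uNA[20]))
  expect_equal(uNA[1:19], rep(1, 19))
})

test_that("suitability components combine multiplicatively with the nil rule", {
  expect_equal(combineSuitabilities(1, 1, 1), 1)
  expect_equal(combineSuitabilities(0.8, 0.5, 1), 0.4)
  expect_equal(combineSuitabilities(0.9, 0.9, 0), 0)
  expect_error(combineSuitabilities(), "at least one")
  # missing component propagates instead of reading as unsuitable
  expect_true(is.na(combineSuitabilities(NA, 0.5, 1)))
})

test_that("daily K composes the three niches per cell and day", {
  env <- oneCellEnv(sstValue = 5.4, depthValue = 100, bloomDays = 20)
  kd <- mdssbDaily(env)
  doy <- as.integer(format(as.Date(kd@time, origin = "1970-01-01"), "%j"))
  onBloom <- doy >= 91 & doy < 111
  expect_true(all(kd@k[1, 1, onBloom] == 1))
  expect_true(all(kd@k[1, 1, !onBloom] == 0))

  envDeep <- oneCellEnv(depthValue = 700)
  expect_true(all(mdssbDaily(envDeep)@k == 0))

  envPoor <- oneCellEnv(background = 0.01, bloomValue = 0.01)
  expect_true(all(mdssbDaily(envPoor)@k == 0))
})

test_that("suitabilities and K stay in [0, 1] on random fields", {
  p <- nicheParameters()
  set.seed(11)
  y <- runif(500, -5, 30); z <- runif(500, -100, 1000)
  u1 <- thermalSuitability(y, p); u2 <- bathymetricSuitability(z, p)
  expect_true(all(u1 >= 0 & u1 <= 1))
  expect_true(all(u2 >= 0 & u2 <= 1))
  k <- combineSuitabilities(u1, u2, rbinom(500, 1, 0.5))
  expect_true(all(k >= 0 & k <= 1))
  expect_true(all(k <= pmin(u1, u2)))
})

test_that("annual averaging uses the productive season and handles gaps", {
  env <- oneCellEnv(bloomDays = 20)
  kd <- mdssbDaily(env)
  # constant daily value averages to itself
  kd2 <- kd; kd2@k[] <- 0.6
  expect_equal(annualizeK(kd2)@k[1, 1, 1], 0.6)
  # fraction of suitable days = mean
  dates <- as.Date(kd@time, origin = "1970-01-01")
  mo <- as.integer(format(dates, "%m"))
  marOct <- mo %in% 3:10
  expectFrac <- mean(kd@k[1, 1, marOct])
  expect_equal(annualizeK(kd)@k[1, 1, 1], expectFrac)
  # all-missing cell-year is missing, not zero
  kd3 <- kd; kd3@k[1, 1, ] <- NA
  expect_true(is.na(annualizeK(kd3)@k[1, 1, 1]))
  expect_false(is.na(annualizeK(kd3)@k[2, 2, 1]))
})

test_that("K is unchanged when chlorophyll is scaled without crossing the threshold", {
  env <- oneCellEnv(bloomDays = 20, background = 0.06, bloomValue = 0.30)
  # all days already at/above threshold; scaling up cannot change U3
  envScaled <- env
  envScaled@chl <- env@chl * 3
  k1 <- annualizeK(mdssbDaily(env))
  k2 <- annualizeK(mdssbDaily(envScaled))
  expect_equal(k1@k, k2@k)
})

test_that("regional series averages box cells; climatology averages years", {
  cfg <- smallConfig(years = 1994:1995)
  env <- makeEnvironment(cfg)
  ka <- annualizeK(mdssbDaily(env))
  bboxAll <- c(min(env@lat), max(env@lat), min(env@lon), max(env@lon))
  # uniform field: the regional mean is the common value
  kaU <- ka; kaU@k[] <- 0.7
  expect_equal(regionalSeries(kaU, bboxAll)@values, c(0.7, 0.7))
  # half the cells at 1, half at 0
  kaH <- ka
  kaH@k[] <- rep(c(1, 0), each = 18)  # 18 of 36 cells per year slice
  expect_equal(regionalSeries(kaH, bboxAll)@values[1], 0.5)
  expect_error(regionalSeries(ka, c(-10, -5, 100, 110)), "does not intersect")

  # climatology: per-cell temporal mean, with missing years counted
  kaC <- ka
  kaC@k[, , 1] <- 0.2; kaC@k[, , 2] <- 0.8
  m <- climatologyMap(kaC)
  expect_true(all(abs(m - 0.5) < 1e-12))
  kaC@k[1, 1, 2] <- NA
  m2 <- climatologyMap(kaC)
  expect_equal(m2[1, 1], 0.2)
  expect_equal(attr(m2, "nYears")[1, 1], 1)
  expect_equal(attr(m2, "nYears")[2, 2], 2)
  expect_error(climatologyMap(ka, c(1800, 1801)), "no years")
})

test_that("niche parameter invariants are enforced", {
  expect_error(nicheParameters(t1 = -1), "t1")
  expect_error(nicheParameters(c = 0), "c must")
  expect_error(nicheParameters(theta3 = 700), "theta")
  expect_error(nicheParameters(windowDays = 0), "windowDays")
})
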