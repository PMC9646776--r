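test_that("the dynamic MSY rule fixes the removal fraction", {
  expect_equal(msyAlpha(1, 0.5, 0.5), 0.25)
  expect_equal(msyAlpha(0.3, 0.5, 0.5), 0.25)   # independent of K
  expect_equal(msyAlpha(1, 0.5, 1), 0)          # no harvest at K
  expect_equal(msyAlpha(1, 0.5, 1e-9), 0.5, tolerance = 1e-6)  # -> r
  expect_error(msyAlpha(1, 0.5, 0), "fraction")
  expect_error(msyAlpha(1, 0.5, 1.2), "fraction")
  expect_error(msyAlpha(0, 0.5), "k must")
})

test_that("MSY holds the stock at or above the target under constant K", {
  set.seed(41)
  for (i in 1:20) {
    k <- runif(1, 0.25, 1); r <- runif(1, 0.2, 0.9)
    tr <- projectCell(rep(k, 120), policyMSY(), r, x0Rule = "K",
                      config = dynamicsConfig(extirpationRuleEnabled = FALSE))
    expect_true(all(tr@x >= k / 2 - 1e-9))
  }
})

test_that("single-cell projections match closed forms and thresholds", {
  # constant alpha = 0.04 on K = 1: equilibrium 1 - 0.04/0.5 = 0.92
  tr <- projectCell(rep(1, 200), policyConstantAlpha(0.04), 0.5)
  expect_true(is.na(tr@extirpatedYear))
  expect_lt(abs(tr@x[200] - 0.92), 1e-6)
  # K below the extirpation threshold dies in year 1
  tr2 <- projectCell(rep(0.05, 10), policyConstantAlpha(0.04), 0.5)
  expect_equal(tr2@extirpatedYear, 1L)
  expect_true(all(tr2@x == 0))
  # declining K: both policies extirpate; the lighter constant removal
  # (0.04 < alpha_MSY = 0.25) keeps biomass higher, so it extirpates no
  # earlier — extirpation year is monotone decreasing in fishing intensity
  kDecl <- seq(0.8, 0.05, length.out = 81)
  trA <- projectCell(kDecl, policyConstantAlpha(0.04), 0.5)
  trM <- projectCell(kDecl, policyMSY(), 0.5)
  expect_false(is.na(trA@extirpatedYear))
  expect_false(is.na(trM@extirpatedYear))
  expect_gte(trA@extirpatedYear, trM@extirpatedYear)
})

test_that("paired maps order extirpation and catch sensibly", {
  # K collapsing earlier in the south -> extirpation years increase northward
  nlat <- 8; nlon <- 3; ny <- 60
  lat <- 51 + (seq_len(nlat) - 0.5) * 0.25
  lon <- 0 + (seq_len(nlon) - 0.5) * 0.25
  k <- array(NA_real_, c(nlat, nlon, ny))
  for (i in seq_len(nlat)) {
    collapseStart <- 0.55 + 0.05 * i   # later/northern rows hold K longer
    k[i, , ] <- rep(pmax(seq(collapseStart, 0.01, length.out = ny), 0.01),
                    each = nlon)
  }
  kf <- new("CarryingCapacityField", lat = lat, lon = lon, k = k,
            time = as.numeric(2020 + seq_len(ny) - 1), timeUnit = "annual")
  ext <- extirpationYearMap(kf, policyConstantAlpha(0.04), 0.5)
  rowYears <- ext[, 1]
  expect_true(all(diff(rowYears) >= 0))
  # heavier MSY removal (0.25 > 0.04) extirpates no later, cell-wise
  extM <- extirpationYearMap(kf, policyMSY(), 0.5)
  both <- !is.na(ext) & !is.na(extM)
  expect_true(all(extM[both] <= ext[both]))

  # pooled catch: zero under a moratorium, positive under MSY, none after
  # extirpation
  catch0 <- pooledCatchMap(kf, policyConstantAlpha(0), 0.5)
  expect_true(all(catch0[!is.na(catch0)] == 0))
  catchM <- pooledCatchMap(kf, policyMSY(), 0.5)
  expect_true(all(catchM[!is.na(catchM)] >= 0))
})

test_that("equilibrium MSY yield accumulates at r K / 4 per year", {
  # constant K = 1, X_MSY = K/2, x0 = K/2: yield is exactly 0.25 * 0.5 per
  # year over the horizon
  tr <- projectCell(rep(1, 81), policyMSY(), 0.5, x0Rule = "halfK")
  expect_equal(sum(tr@catch), 81 * 0.125)
  # one-year horizon books a single removal alpha * x0
  tr1 <- projectCell(rep(1, 1), policyConstantAlpha(0.04), 0.5, x0Rule = "K")
  expect_equal(sum(tr1@catch), 0.04 * 1)
})

test_that("scenario comparison reports medians over the box", {
  lat <- 51 + (1:4 - 0.5) * 0.25; lon <- 0 + (1:4 - 0.5) * 0.25
  a <- matrix(2040, 4, 4); b <- a + 5
  cmp <- compareScenarios(a, b, lat, lon, bbox = c(51, 62, -3, 9.5))
  expect_equal(cmp$median, 5)
  expect_equal(compareScenarios(a, a, lat, lon)$median, 0)
  # catch halved everywhere -> 50% reduction
  ca <- matrix(10, 4, 4); cb <- ca / 2
  expect_equal(compareScenarios(ca, cb, lat, lon, type = "catch")$median, 50)
  # censoring: never-extirpating cells drop out of year medians
  a2 <- a; a2[1, 1] <- NA
  cmp2 <- compareScenarios(a2, b, lat, lon)
  expect_equal(length(cmp2$differences), 15)
  cmp3 <- compareScenarios(a2, b, lat, lon, censor = "horizon",
                           horizon = 2100)
  expect_equal(length(cmp3$differences), 16)
  expect_error(compareScenarios(a, matrix(1, 2, 2), lat, lon), "grids")
  expect_error(compareScenarios(a, b, lat, lon, bbox = c(0, 1, 0, 1)),
               "misses")
})
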