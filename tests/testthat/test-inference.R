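test_that("fishing intensity inversion is the exact algebraic inverse of the map", {
  expect_equal(estimateAlpha(c(0.2, 0.23), 0.4, 0.5), 0.1,
               ignore_attr = TRUE)
  # round trip on a clean simulation
  set.seed(31)
  k <- runif(30, 0.4, 1)
  alpha <- runif(30, 0, 0.4)
  tr <- simulateStock(0.2, k, alpha, 0.5)
  ahat <- estimateAlpha(tr@x, k, 0.5)
  expect_lt(max(abs(ahat - alpha[1:29])), 1e-12)
  # unfished trajectory inverts to zero
  tr0 <- simulateStock(0.2, rep(0.8, 20), 0, 0.5)
  expect_lt(max(abs(estimateAlpha(tr0@x, rep(0.8, 20), 0.5))), 1e-12)
  expect_error(estimateAlpha(c(0.2, 0), 0.4, 0.5), "positive")
  expect_error(estimateAlpha(0.2, 0.4, 0.5), "length")
})

test_that("out-of-range intensity estimates are flagged, not silently dropped", {
  # an impossible jump implies alpha < 0
  a <- estimateAlpha(c(0.1, 0.9), 1, 0.5)
  expect_true(attr(a, "flagged")[1])
  expect_lt(a[1], 0)
})

test_that("SSB standardisation recovers a self-consistent construction", {
  set.seed(32)
  n <- 40
  k <- runif(n, 0.5, 0.7)
  alphaTrue <- 0.15 + 0.2 * exp(-((seq(0, 1, length.out = n) - 0.6) / 0.2)^2)
  tr <- simulateStock(0.25, k, alphaTrue, 0.5)
  logSsb <- 2 * tr@x + 3          # affine disguise
  f <- alphaTrue[1:(n - 1)]       # effort equals the truth
  std <- standardiseSsb(logSsb, k, f, r = 0.5, gridN = 80)
  expect_true(std@feasible)
  expect_gte(std@objective, 0.999)
  expect_true(all(std@x > 0 & std@x < min(k)))
  ahat <- estimateAlpha(std@x, k, 0.5)
  expect_gte(cor(ahat, f), 0.999)
})

test_that("degenerate standardisation inputs are rejected", {
  expect_error(standardiseSsb(rep(1, 10), rep(0.5, 10), runif(10)),
               "constant")
  expect_error(standardiseSsb(runif(10), c(rep(0.5, 9), 0), runif(10)),
               "feasible")
  expect_error(standardiseSsb(runif(10), rep(0.5, 10), rep(0.2, 10)),
               "variance")
})

makeSet <- function(n = 30, seed = 33, kConst = NULL, alphaConst = NULL) {
  set.seed(seed)
  k <- if (is.null(kConst)) runif(n, 0.5, 1) else rep(kConst, n)
  alpha <- if (is.null(alphaConst)) runif(n, 0.05, 0.35) else rep(alphaConst, n)
  reconstructCounterfactuals(0.3, k, alpha, 0.5)
}

test_that("counterfactuals collapse onto the full run when forcing is constant", {
  sAlpha <- makeSet(alphaConst = 0.2)
  expect_equal(sAlpha@alphaMinFixed@x, sAlpha@full@x)
  expect_equal(sAlpha@alphaMaxFixed@x, sAlpha@full@x)
  sK <- makeSet(kConst = 0.8)
  expect_equal(sK@kMinFixed@x, sK@full@x)
  expect_equal(sK@kMaxFixed@x, sK@full@x)
})

test_that("the full trajectory lies inside the counterfactual envelope after burn-in", {
  s <- makeSet(n = 50)
  env <- rbind(s@alphaMinFixed@x, s@alphaMaxFixed@x, s@kMinFixed@x,
               s@kMaxFixed@x)
  lo <- apply(env, 2, min); hi <- apply(env, 2, max)
  burn <- 11:50
  expect_true(all(s@full@x[burn] >= lo[burn] - 1e-9))
  expect_true(all(s@full@x[burn] <= hi[burn] + 1e-9))
})

test_that("influence series vanish when the matching forcing is constant", {
  sK <- makeSet(kConst = 0.8)
  expect_true(all(abs(influenceSeries(sK)$fishing) < 1e-12))
  sA <- makeSet(alphaConst = 0.2)
  expect_true(all(abs(influenceSeries(sA)$environment) < 1e-12))
  # with both forcings varying, both residual series carry signal
  set.seed(36)
  s <- makeSet(n = 40)
  infl <- influenceSeries(s)
  expect_gt(max(abs(infl$fishing)), 0.01)
  expect_gt(max(abs(infl$environment)), 0.01)
})

test_that("the fishing-influence index is directional and bounded", {
  # minimal fishing throughout + degraded environment: influence well below 50
  n <- 40
  kDegraded <- seq(0.9, 0.3, length.out = n)
  sEnv <- reconstructCounterfactuals(0.3, kDegraded, rep(0.05, n), 0.5)
  aEnv <- influenceIndex(sEnv)
  expect_lt(aEnv@epsilon, 50)
  # heavy, varying fishing at the best constant environment: all fishing
  set.seed(34)
  sFish <- reconstructCounterfactuals(0.3, rep(0.9, n),
                                      runif(n, 0.2, 0.45), 0.5)
  aFish <- influenceIndex(sFish)
  expect_gt(aFish@epsilon, 50)
  # bounds and jackknife ordering on a mixed scenario
  s <- makeSet(n = 40)
  a <- influenceIndex(s)
  expect_true(a@epsilon >= 0 && a@epsilon <= 100)
  expect_lte(a@jackknifeMin, a@jackknifeMean)
  expect_lte(a@jackknifeMean, a@jackknifeMax)
  expect_true(a@epsilon >= a@jackknifeMin && a@epsilon <= a@jackknifeMax)
  # gamma = delta gives exactly 50; both readings are exposed
  aSwap <- influenceIndex(s, mapping = "swapped")
  expect_equal(aSwap@gamma, a@delta)
  expect_equal(aSwap@delta, a@gamma)
  expect_equal(a@epsilon + aSwap@epsilon, 100)
})

test_that("jackknife enumerates leave-one-out years", {
  s <- makeSet(n = 12)
  jk <- jackknifeEpsilon(s)
  expect_lte(jk[["min"]], jk[["mean"]])
  expect_lte(jk[["mean"]], jk[["max"]])
  # three-year period runs exactly three replicates; errors below that
  yrs <- s@full@years
  jk3 <- jackknifeEpsilon(s, c(yrs[1], yrs[3]))
  expect_true(all(is.finite(jk3)))
  expect_error(jackknifeEpsilon(s, c(yrs[1], yrs[2])), "at least 3")
})

test_that("period identification recovers piecewise-constant regimes", {
  set.seed(35)
  n <- 30
  level <- rep(c(0, 0.5, 1), each = 10)
  mat <- cbind(level, level, level) + matrix(rnorm(3 * n, 0, 0.02), n, 3)
  per <- identifyPeriods(mat, kGroups = 3, years = 1981:2010)
  expect_equal(nrow(per), 3)
  expect_equal(per$start, c(1981, 1991, 2001))
  expect_equal(per$end, c(1990, 2000, 2010))
  # degenerate cuts
  expect_equal(nrow(identifyPeriods(mat, kGroups = 1)), 1)
  expect_equal(nrow(identifyPeriods(mat, kGroups = n)), n)
  expect_error(identifyPeriods(mat, kGroups = n + 1), "exceed")
  # invariant to column order and to uniform affine rescaling
  perm <- identifyPeriods(mat[, c(3, 1, 2)], kGroups = 3, years = 1981:2010)
  expect_equal(per, perm)
  scaled <- identifyPeriods(10 * mat + 4, kGroups = 3, years = 1981:2010)
  expect_equal(per, scaled)
})
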