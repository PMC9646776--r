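test_that("one step of the harvested logistic map is exact", {
  expect_equal(stepStock(0.5, 1, 0.5, 0), 0.625)
  expect_equal(stepStock(0.7, 0.7, 0.5, 0), 0.7)   # fixed point at K
  expect_equal(stepStock(0.2, 0.4, 0.5, 0.1), 0.23)
  # K = 0: growth term taken at its limit 0, removal still applies
  expect_equal(stepStock(0.3, 0, 0.5, 0.2), 0.3 - 0.2 * 0.3)
})

test_that("closed-form equilibrium matches and floors at zero", {
  expect_equal(equilibriumDssb(1, 0.5, 0.25), 0.5)
  expect_equal(equilibriumDssb(0.8, 0.5, 0), 0.8)
  expect_equal(equilibriumDssb(1, 0.5, 0.5), 0)
  expect_equal(equilibriumDssb(1, 0.5, 0.9), 0)  # alpha > r floors
})

test_that("unfished trajectories rise monotonically to K without overshoot", {
  set.seed(21)
  for (i in 1:25) {
    r <- runif(1, 0.05, 1); k <- runif(1, 0.2, 1)
    x0 <- runif(1, 0.01, k)
    tr <- simulateStock(x0, rep(k, 60), 0, r)
    expect_true(all(diff(tr@x) >= -1e-14))
    expect_true(all(tr@x <= k + 1e-12))
  }
})

test_that("constant forcing converges to the closed-form equilibrium", {
  set.seed(22)
  for (i in 1:25) {
    r <- runif(1, 0.15, 1); k <- runif(1, 0.2, 1)
    alpha <- runif(1, 0, r - 0.05)  # a margin keeps convergence geometric
    tr <- simulateStock(0.5 * k, rep(k, 500), alpha, r)
    expect_lt(abs(tr@x[500] - equilibriumDssb(k, r, alpha)), 1e-6)
  }
})

test_that("the extirpation rule is absorbing and dated", {
  cfg <- dynamicsConfig(extirpationRuleEnabled = TRUE)
  # equilibrium K(1 - alpha/r) = 0.08 sits below the threshold: the
  # decline crosses 0.1 and extirpates in finite time
  tr <- simulateStock(0.5, rep(1, 400), 0.46, 0.5, cfg)
  expect_false(is.na(tr@extirpatedYear))
  after <- tr@years > tr@extirpatedYear
  expect_true(all(tr@x[after] == 0))
  expect_true(all(tr@x[tr@years < tr@extirpatedYear] > 0.1))

  # full removal collapses the stock within two steps
  # (0.5 -> 0.5 + 0.125 - 0.5 = 0.125 -> growth only 0.0547 <= 0.1)
  tr2 <- simulateStock(0.5, rep(1, 10), 1, 0.5, cfg)
  expect_equal(tr2@x[2], 0.125)
  expect_equal(tr2@extirpatedYear, 3L)
  expect_true(all(tr2@x[tr2@years >= 3] == 0))

  # historical default leaves the rule off: the state just decays
  tr3 <- simulateStock(0.5, rep(1, 400), 0.46, 0.5)
  expect_true(is.na(tr3@extirpatedYear))
  expect_gt(tr3@x[400], 0)
})

test_that("constant-catch simulation reaches the surplus-production root", {
  # catch 0 is the unfished map
  a <- simulateStock(0.4, rep(0.9, 50), 0, 0.5)
  b <- simulateConstantCatch(0.4, rep(0.9, 50), 0, 0.5)
  expect_equal(a@x, b@x)
  # equilibrium solves r x (1 - x/K) = catch; take the upper root
  r <- 0.5; catch <- 0.03
  roots <- sort(Re(polyroot(c(catch, -r, r))))  # r x^2 - r x + catch = 0
  upper <- max(roots)
  tr <- simulateConstantCatch(0.8, rep(1, 400), catch, r)
  expect_lt(abs(tr@x[400] - upper), 1e-8)
  # declining K under constant catch forces extirpation
  kDecl <- seq(1, 0.12, length.out = 120)
  tr2 <- simulateConstantCatch(0.8, kDecl, catch, r,
                               dynamicsConfig(extirpationRuleEnabled = TRUE))
  expect_false(is.na(tr2@extirpatedYear))
})

test_that("recovery time follows the moratorium convention", {
  # monotone in r; divergence as K approaches the target from above
  expect_gt(recoveryTime(1, 0.25), recoveryTime(1, 0.5))
  expect_gt(recoveryTime(1, 0.5), recoveryTime(1, 0.75))
  expect_gt(recoveryTime(0.401, 0.5), recoveryTime(0.6, 0.5))
  expect_gt(recoveryTime(0.4001, 0.5), recoveryTime(0.401, 0.5))
  expect_identical(recoveryTime(0.4, 0.5), Inf)   # target equals K
  expect_identical(recoveryTime(0.3, 0.5), Inf)   # target above K
  expect_equal(recoveryTime(1, 0.5, target = 0.05, x0 = 0.1), 1)
})

test_that("collapse is relative to the unfished biomass", {
  expect_true(isCollapsed(0.05, 1))
  expect_false(isCollapsed(0.11, 1))
  expect_false(isCollapsed(0.03, 0.2))  # 0.03 > 0.1 * 0.2
  expect_true(isCollapsed(0.02, 0.2))
})

test_that("misaligned or invalid simulation inputs error", {
  expect_error(simulateStock(0.5, rep(1, 10), rep(0.1, 5), 0.5), "align")
  expect_error(simulateStock(0.5, rep(1, 10), 0.1, 0.5, years = 1:3), "align")
  expect_error(simulateStock(-1, rep(1, 10), 0.1, 0.5))
  expect_error(dynamicsConfig(extirpationThreshold = 1.5), "extirpationThreshold")
})
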