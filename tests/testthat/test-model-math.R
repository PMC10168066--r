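test_that("overall temperature effect is the moisture-scaled linear form", {
  expect_equal(overallTemperatureEffect(1.0, 0.05, 20), 2.0)
  expect_equal(overallTemperatureEffect(0.7, 0.03, 0), 0.7)
  # with zero interaction the overall effect equals the temperature
  # coefficient alone (the seasonal-minimum case reported for cypress)
  expect_equal(overallTemperatureEffect(0.435, 0, 33), 0.435)
  # linearity in both coefficients
  expect_equal(overallTemperatureEffect(2 * 0.3, 2 * 0.01, 15),
               2 * overallTemperatureEffect(0.3, 0.01, 15))
})

test_that("exogenous effect is the log-gap power and guards the domain", {
  expect_equal(exogenousEffect(1.0, exp(1) + 4, 4), 1.0)
  expect_equal(exogenousEffect(1.5, 14, 4), 1.5 * log(10))
  expect_equal(exogenousEffect(1.5, 14, 4), 3.45388, tolerance = 1e-5)
  expect_equal(exogenousEffect(2.0, 5, 4), 0.0)
  expect_error(exogenousEffect(1, 4, 4), "stmin")
  expect_error(exogenousEffect(1, 4.005, 4), "stmin") # inside the guard
  # sign flips in the fractional-gap region
  expect_lt(exogenousEffect(1, 4.5, 4), 0)
  expect_gt(exogenousEffect(1, 6, 4), 0)
})

test_that("growth rate switches regimes at the threshold", {
  # below threshold only the baseline remains
  expect_equal(growthRate(le = 3, betaSt = 2, betaSm = 1, SM = 30,
                          ST = 2, stmin = 4, betaBase = 0.001), 0.001)
  # above threshold: exp(le + ex) + baseline
  expect_equal(growthRate(0, 1, 0, 10, exp(1) + 4, 4, 0.001),
               exp(1) + 0.001)
  expect_equal(growthRate(0, 1, 0, 10, exp(1) + 4, 4, 0.001), 2.71928,
               tolerance = 1e-5)
  # vanishing latent effect leaves the baseline
  expect_equal(growthRate(-745, 1, 0, 10, exp(1) + 4, 4, 0.002), 0.002)
  # never below the baseline on a mixed path
  ST <- seq(0, 30, by = 1)
  b <- growthRate(-2, 1, 0.02, 20, ST, 4, 1e-3)
  expect_true(all(b >= 1e-3))
})

test_that("threshold regime is continuous: response vanishes as the gap closes", {
  for (gap in c(1e-3, 1e-6)) {
    beta <- growthRate(le = 0, betaSt = 1, betaSm = 0, SM = 0,
                       ST = 4 + gap, stmin = 4, betaBase = 5e-4, eps = 0)
    expect_equal(beta, 5e-4, tolerance = 2 * gap / 5e-4)
    expect_lt(abs(beta - 5e-4), 2 * gap)
  }
})

test_that("production is increasing in temperature when the effect is positive", {
  ST <- seq(5, 30, by = 0.5)
  p <- meanProduction(growthRate(-3, 0.8, 0.02, 25, ST, 4, 1e-4), 1.5)
  expect_true(all(diff(p) > 0))
})

test_that("mean production multiplies rate and standing area", {
  expect_equal(meanProduction(0, 5), 0)
  expect_equal(meanProduction(0.01, 2), 0.02)
  expect_equal(meanProduction(1e-4, 3.7), 1e-4 * 3.7)
})

test_that("biomass propagation follows the mass balance step", {
  expect_equal(propagateBiomass(1, 0.01, 0.005, 10), 1.05)
  expect_equal(propagateBiomass(3.2, 0.007, 0.007, 8), 3.2)
  expect_error(propagateBiomass(1, 0, 0.2, 10),
               class = "rootSSM_positivity")
})

test_that("trajectory composes steps exactly and reports offending index", {
  fo <- tinyForcing(ST = c(10, 12, 14), V = c(10, 10, 10))
  # force beta path {0.01, 0.02} via fixed le with zero coefficients
  sc <- scalarParams(b1 = 1, gamma = 0.005, betaBase = 0, stmin = 4)
  le <- log(c(0.01, 0.02, 0.02))
  traj <- biomassTrajectory(fo, le, rep(0, 3), rep(0, 3), sc)
  expect_equal(traj@b, c(1, 1.05, 1.2075))
  # mortality overwhelming growth over one interval is inadmissible
  scBad <- scalarParams(b1 = 1, gamma = 0.15, betaBase = 0, stmin = 4)
  err <- tryCatch(
    biomassTrajectory(fo, log(c(1e-9, 1e-9, 1e-9)), rep(0, 3), rep(0, 3),
                      scBad),
    rootSSM_positivity = conditionMessage)
  expect_match(err, "period index 2")
})

test_that("all-below-threshold forcing gives pure baseline production", {
  fo <- tinyForcing(ST = rep(1, 8))
  sc <- scalarParams(b1 = 2, gamma = 0.001, betaBase = 3e-4, stmin = 4)
  traj <- biomassTrajectory(fo, rnorm(8), rnorm(8), rnorm(8), sc)
  expect_equal(traj@p, 3e-4 * traj@b)
  # closed-form geometric growth of b
  expect_equal(traj@b,
               2 * cumprod(c(1, rep(1 + (3e-4 - 0.001) * 10, 7))))
})

test_that("mass balance closes to machine precision on random trajectories", {
  for (seed in 1:20) {
    set.seed(seed)
    T <- sample(10:60, 1)
    fo <- tinyForcing(ST = runif(T, 0, 28), SM = runif(T, 5, 45),
                      V = sample(8:11, T, replace = TRUE))
    sc <- scalarParams(b1 = runif(1, 0.5, 3), gamma = runif(1, 0, 0.008),
                       betaBase = runif(1, 0, 5e-4), stmin = 4)
    traj <- biomassTrajectory(fo, rnorm(T, -7, 1), runif(T, 0.3, 1.2),
                              runif(T, 0, 0.05), sc)
    beta <- growthRatePath(traj, fo)
    flux <- sum((traj@p - sc@gamma * traj@b)[-T] * fo$V[-T])
    expect_equal(traj@b[T] - traj@b[1], flux,
                 tolerance = 1e-12 * max(1, abs(flux)))
    expect_equal(traj@p, beta * traj@b)
  }
})
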