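test_that("forcing generator respects seasonal bounds and the dekadal calendar", {
  cf <- syntheticConfig(years = 2, tempMean = 15, tempAmp = 12,
                        tempNoiseSd = 0, seed = 3)
  fo <- generateForcing(cf)
  expect_equal(nrow(fo$forcing), 72)       # 36 periods per year
  expect_true(all(fo$forcing$ST >= 3 - 1e-9 & fo$forcing$ST <= 27 + 1e-9))
  expect_true(all(fo$forcing$SM > 0 & fo$forcing$SM < 100))
  expect_equal(sum(fo$forcing$V[1:36]), 365)
  # determinism under the same seed
  fo2 <- generateForcing(cf)
  expect_identical(fo, fo2)
})

test_that("dekadal forcing equals the mean of its daily values exactly", {
  cf <- syntheticConfig(years = 1, seed = 5)
  fo <- generateForcing(cf)
  dk <- dekadOfDate(fo$daily$date)
  key <- dekadLabel(dk)
  stMean <- tapply(fo$daily$soil_temp_c, key, mean)
  lbl <- dekadLabel(fo$forcing)
  expect_equal(as.numeric(stMean[lbl]), fo$forcing$ST, tolerance = 1e-12)
})

test_that("degenerate random walks give constant paths", {
  cf <- syntheticConfig(years = 1, pathSpec = "random_walk",
                        scalars = scalarParams(sigmaLe = 1e-12,
                                               sigmaSt = 1e-12,
                                               sigmaSm = 1e-12),
                        seed = 4)
  fo <- generateForcing(cf)
  traj <- simulateLatent(fo$forcing, cf$scalars, cf, seed = 9)
  expect_lt(diff(range(traj@betaSt)), 1e-9)
  expect_lt(diff(range(traj@betaSm)), 1e-9)
  expect_lt(diff(range(traj@le)), 1e-9)
})

test_that("zero interaction makes production independent of moisture", {
  cf <- syntheticConfig(years = 1, pathSpec = "fixed", le0 = -7, seed = 2)
  fo <- generateForcing(cf)
  T <- nrow(fo$forcing)
  fp <- list(le = rep(-7, T), betaSt = rep(0.8, T), betaSm = rep(0, T))
  cf$fixedPaths <- fp
  t1 <- simulateLatent(fo$forcing, cf$scalars, cf, seed = 1)
  foAlt <- fo$forcing
  foAlt$SM <- rev(foAlt$SM) # scramble moisture
  t2 <- simulateLatent(foAlt, cf$scalars, cf, seed = 1)
  expect_equal(t1@p, t2@p)
})

test_that("all-below-threshold forcing yields baseline-only production", {
  cf <- syntheticConfig(years = 1, tempMean = -5, tempAmp = 2,
                        tempNoiseSd = 0, le0 = -7, seed = 2)
  fo <- generateForcing(cf)
  traj <- simulateLatent(fo$forcing, cf$scalars, cf, seed = 1)
  expect_equal(traj@p / traj@b,
               rep(cf$scalars@betaBase, nrow(fo$forcing)))
})

test_that("observation hierarchy has the right mean and collapses as rates grow", {
  fo <- tinyForcing(ST = c(15, 15))
  sc <- scalarParams(b1 = 1, gamma = 0, betaBase = 0, stmin = 4)
  traj <- biomassTrajectory(fo, log(c(0.02, 0.02)), c(0, 0), c(0, 0), sc)
  # vanishing-dispersion limit: the per-level CV is 1/sqrt(lambda * p),
  # so rates of 1e8 at p = 0.02 put every record within 1% of p
  so <- simulateObservations(traj, S = 3, C = 4, lambdaT = 1e8,
                             lambdaS = 1e8, seed = 8)
  pt <- traj@p[so$observations$t]
  expect_true(all(abs(so$observations$production - pt) / pt < 0.01))
  # law of large numbers at one period: grand mean within 3 SE of p_t
  so2 <- simulateObservations(traj, S = 1, C = 1e5, cvScanner = 1e-6,
                              cvImage = 0.3, seed = 9)
  F1 <- so2$observations$production[so2$observations$t == 1]
  se <- sd(F1) / sqrt(length(F1))
  expect_lt(abs(mean(F1) - traj@p[1]), 3 * se)
})

test_that("missingness is binomial at the configured rate", {
  cf <- syntheticConfig(years = 1, S = 5, C = 4, missingnessRate = 0.2,
                        seed = 21)
  st <- makeSyntheticStudy(cf)
  n <- nrow(st@observations)
  total <- 36 * 5 * 4 # 720 candidate records
  q <- qbinom(c(0.005, 0.995), total, 0.8)
  expect_gte(n, q[1])
  expect_lte(n, q[2])
})

test_that("study composition is reproducible and respects invariants", {
  cf <- syntheticConfig(years = 1, S = 2, C = 2, seed = 31)
  s1 <- makeSyntheticStudy(cf)
  s2 <- makeSyntheticStudy(cf)
  expect_identical(s1@observations, s2@observations)
  expect_identical(s1@truth@p, s2@truth@p)
  expect_true(validObject(s1@truth))
  expect_true(validObject(s1@experiment))
  expect_true(all(s1@truth@b > 0))
  # byte-identical CSV output under the same seed
  d1 <- tempfile(); d2 <- tempfile()
  writeSyntheticStudy(s1, d1); writeSyntheticStudy(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("a four-year five-scanner study has the expected shape", {
  cf <- syntheticConfig(years = 4, S = 5, C = 8, missingnessRate = 0,
                        seed = 13)
  st <- makeSyntheticStudy(cf)
  expect_equal(nrow(st@forcing), 144)
  expect_lte(nrow(st@observations), 5760)
  expect_equal(nrow(st@observations), 144 * 5 * 8) # no missingness
})
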