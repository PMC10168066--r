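test_that("effect series: zero interaction collapses onto the temperature effect", {
  fo <- tinyForcing(ST = runif(12, 6, 25), SM = runif(12, 10, 40))
  set.seed(2)
  nd <- 200
  le <- matrix(rnorm(nd * 12, -6, 0.2), nd)
  bst <- matrix(rnorm(nd * 12, 0.9, 0.1), nd)
  bsm0 <- matrix(0, nd, 12)
  fit <- fakeFit(le, bst, bsm0, fo)
  es <- effectSeries(fit, fo)
  sm <- es[es$quantity == "smContribution", ]
  expect_true(all(sm$q50 == 0) && all(sm$q97.5 == 0))
  expect_equal(es[es$quantity == "betaExt", "q50"],
               es[es$quantity == "betaSt", "q50"])
})

test_that("a single draw gives degenerate (zero-width) bands", {
  fo <- tinyForcing(ST = 15, SM = 20, V = 10)[c(1, 1), ]
  fo$tercile <- 1:2
  fit <- fakeFit(matrix(-6, 2, 2), matrix(1, 2, 2), matrix(0.05, 2, 2),
                 fo)
  es <- effectSeries(fit, fo)
  be <- es[es$quantity == "betaExt", ]
  expect_equal(be$q50, c(2, 2))   # 1 + 0.05 * 20
  expect_equal(be$q2.5, be$q97.5) # no posterior spread
})

test_that("derived effects are computed draw-wise, not from marginal medians", {
  fo <- tinyForcing(ST = 15, SM = 30, V = 10)[c(1, 1), ]
  set.seed(5)
  nd <- 4000
  # strongly skewed, anticorrelated draws: the median of the sum is far
  # from the sum of the medians
  bst <- matrix(rep(rlnorm(nd, 0, 1), 2), nd)
  bsm <- matrix(rep(-rlnorm(nd, -3, 1.2), 2), nd)
  fit <- fakeFit(matrix(-6, nd, 2), bst, bsm, fo)
  es <- effectSeries(fit, fo)
  drawWise <- median(bst[, 1] + bsm[, 1] * 30)
  marginal <- median(bst[, 1]) + median(bsm[, 1]) * 30
  expect_equal(es[es$quantity == "betaExt", "q50"][1], drawWise)
  expect_gt(abs(drawWise - marginal), 1e-3)
})

test_that("regression curves reproduce the model math at observed forcing", {
  set.seed(3)
  fo <- tinyForcing(ST = runif(6, 8, 25), SM = runif(6, 15, 35))
  nd <- 50
  le <- matrix(rnorm(nd * 6, -6, 0.3), nd)
  bst <- matrix(runif(nd * 6, 0.5, 1.2), nd)
  bsm <- matrix(runif(nd * 6, 0, 0.05), nd)
  fit <- fakeFit(le, bst, bsm, fo)
  for (t in c(1, 4)) {
    rc <- regressionCurves(fit, fo, periods = t,
                           STgrid = fo$ST[t], probs = 0.5)
    pDraws <- paramDraws(fit, "p")[, t]
    expect_equal(rc$q50, median(pDraws), tolerance = 1e-12)
  }
  # unit-gap identity: at ST = stmin + 1 the power term is exp(le)
  rc1 <- regressionCurves(fit, fo, periods = 2, STgrid = 5, probs = 0.5)
  expect_equal(rc1$q50,
               median((exp(le[, 2]) + 1e-4) * 1), tolerance = 1e-12)
  # flat curve above threshold when the exponent is zero
  fit0 <- fakeFit(le, matrix(0, nd, 6), matrix(0, nd, 6), fo)
  rc0 <- regressionCurves(fit0, fo, periods = 3,
                          STgrid = c(6, 12, 25), probs = 0.5)
  expect_equal(rc0$q50[1], rc0$q50[2])
  expect_equal(rc0$q50[2], rc0$q50[3])
})

test_that("percent change per 1% soil moisture follows the power-law form", {
  expect_equal(percentChangePerSM(0, 20, 4), 0)
  expect_equal(percentChangePerSM(0.05, 14, 4), 100 * (10^0.05 - 1))
  expect_equal(percentChangePerSM(0.05, 14, 4), 12.2018, tolerance = 1e-4)
  expect_error(percentChangePerSM(0.05, 3, 4), "stmin")
  # the reported ~17% per 1% SM at the 2011 cypress peak (betaSm = 0.062)
  # back-solves to a temperature gap of about 12.6 degC
  gap <- exp(log(1.17) / 0.062)
  expect_equal(gap, 12.6, tolerance = 0.01)
  expect_equal(percentChangePerSM(0.062, gap + 4, 4), 17, tolerance = 1e-6)
  # exact variant approaches the power-law form as the baseline vanishes
  ex <- percentChangePerSM(0.05, 14, 4, exact = TRUE, le = -5,
                           betaSt = 1, SM = 20, betaBase = 1e-12)
  expect_equal(ex, percentChangePerSM(0.05, 14, 4), tolerance = 1e-4)
  # and is damped by a large baseline
  exBig <- percentChangePerSM(0.05, 14, 4, exact = TRUE, le = -5,
                              betaSt = 1, SM = 20, betaBase = 1)
  expect_lt(exBig, percentChangePerSM(0.05, 14, 4))
})

test_that("production report nests bands and finds injected peaks", {
  cf <- syntheticConfig(years = 1, S = 2, C = 2, seed = 23)
  st <- makeSyntheticStudy(cf)
  fo <- st@forcing
  T <- nrow(fo)
  set.seed(8)
  nd <- 100
  # a latent path with a single spring bump (period 13 of the year)
  leBase <- rep(-8, T); leBase[10:16] <- -8 + c(1, 2, 3, 4, 3, 2, 1)
  le <- matrix(rep(leBase, each = nd), nd) + rnorm(nd * T, 0, 0.05)
  fit <- fakeFit(le, matrix(0.0, nd, T), matrix(0, nd, T), fo)
  rep <- productionReport(fit, st@experiment)
  expect_true(all(rep$table$q25 >= rep$table$q2.5))
  expect_true(all(rep$table$q75 <= rep$table$q97.5))
  expect_true(13 %in% rep$peaks$t)
  expect_equal(rep$peaks$median[rep$peaks$t == 13],
               max(rep$table$q50))
})
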