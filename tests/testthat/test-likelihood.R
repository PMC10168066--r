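test_that("hierarchical gamma log-likelihood matches closed forms", {
  # Gamma(shape 2, rate 2) at 1: log(4 e^-2)
  fo <- tinyForcing(ST = c(10, 12))
  obs <- data.frame(t = 1L, scanner = 1L, image = 1L, production = 1)
  p <- c(0.5, 0.5)
  ps <- matrix(1, 2, 1)
  lambdaS <- matrix(2, 2, 1) # shape = 2*1 = 2, rate = 2
  ll <- hierGammaLogLik(obs, ps, lambdaT = c(1, 1), lambdaS, p)
  expect_equal(ll$pointwise, log(4) - 2)
  expect_equal(ll$pointwise, -0.61371, tolerance = 1e-5)
  # mean identity of the hierarchy: shape/rate = p by construction
  lamT <- 7.3
  expect_equal((lamT * p) / lamT, p)
  # missing records contribute nothing
  ll0 <- hierGammaLogLik(obs[0, ], ps, c(1, 1), lambdaS, p)
  expect_length(ll0$pointwise, 0)
  expect_equal(ll0$total, sum(ll0$scannerLevel))
  expect_error(hierGammaLogLik(obs, ps, c(-1, 1), lambdaS, p),
               "positive")
})

test_that("zero observations are left-censored at delta", {
  obs <- data.frame(t = c(1L, 1L), scanner = c(1L, 1L), image = 1:2,
                    production = c(0, 0.4))
  ps <- matrix(0.5, 2, 1)
  lambdaS <- matrix(10, 2, 1)
  ll <- hierGammaLogLik(obs, ps, c(1, 1), lambdaS, c(0.5, 0.5))
  # delta defaults to half the smallest positive record
  expect_equal(ll$pointwise[1],
               pgamma(0.2, shape = 5, rate = 10, log.p = TRUE))
  llo <- hierGammaLogLik(obs, ps, c(1, 1), lambdaS, c(0.5, 0.5),
                         zeroRule = "offset")
  expect_equal(llo$pointwise[1],
               dgamma(0.2, shape = 5, rate = 10, log = TRUE))
})

test_that("random-walk log prior sums step densities plus initialisation", {
  expect_equal(randomWalkLogPrior(c(0, 1), 1),
               dnorm(1, 0, 1, log = TRUE))
  expect_equal(randomWalkLogPrior(c(0, 1), 1), -1.41894,
               tolerance = 1e-5)
  # zero increments: T-1 copies of the mode density
  T <- 9
  expect_equal(randomWalkLogPrior(rep(2, T), 0.3),
               (T - 1) * dnorm(0, 0, 0.3, log = TRUE))
  # doubling sigma at zero increments lowers each step term by log 2
  expect_equal(randomWalkLogPrior(rep(2, T), 0.6) -
                 randomWalkLogPrior(rep(2, T), 0.3),
               -(T - 1) * log(2))
  # initialisation prior adds a single normal term
  expect_equal(randomWalkLogPrior(c(0.5, 1), 1, initMean = 0, initSd = 2) -
                 randomWalkLogPrior(c(0.5, 1), 1),
               dnorm(0.5, 0, 2, log = TRUE))
})

test_that("log posterior equals the naive-loop oracle on small instances", {
  pr <- priorConfig()
  for (seed in 1:5) {
    set.seed(seed)
    T <- 6; S <- 2; C <- 2
    fo <- tinyForcing(ST = runif(T, 2, 20), SM = runif(T, 10, 40),
                      V = sample(8:11, T, replace = TRUE))
    q <- tinyParams(T, S, seed = seed)
    obs <- tinyObs(T, S, C, seed = seed + 100)
    got <- logPosterior(q, fo, obs, stmin = 4, priors = pr)
    want <- naiveLogPosterior(q, fo, obs, stmin = 4, pr = pr)
    expect_equal(got$logPost, want$logPost, tolerance = 1e-10)
    expect_equal(got$pointwise, want$pointwise, tolerance = 1e-10)
  }
})

test_that("log posterior without observations reduces to the prior", {
  T <- 6; S <- 2
  fo <- tinyForcing(ST = runif(T, 5, 20))
  q <- tinyParams(T, S)
  obs0 <- tinyObs(T, S, 2)[0, ]
  got <- logPosterior(q, fo, obs0, stmin = 4)
  # no observation terms: total = prior + scanner-level hierarchy
  expect_length(got$pointwise, 0)
  expect_equal(got$logPost, got$logPrior + got$logLik)
})

test_that("pointwise table sums to the observation part of the likelihood", {
  T <- 6; S <- 2
  fo <- tinyForcing(ST = runif(T, 5, 20))
  q <- tinyParams(T, S)
  obs <- tinyObs(T, S, 2)
  noObs <- logPosterior(q, fo, obs[0, ], stmin = 4)
  full <- logPosterior(q, fo, obs, stmin = 4)
  expect_equal(full$logPost - noObs$logPost, sum(full$pointwise),
               tolerance = 1e-10)
})

test_that("inadmissible parameters are rejected with -Inf, not an error", {
  T <- 4; S <- 2
  fo <- tinyForcing(ST = rep(15, T))
  q <- tinyParams(T, S)
  q$gamma <- 0.15 # overwhelms growth: positivity violation
  q$le <- rep(-30, T)
  expect_identical(logPosterior(q, fo, tinyObs(T, S, 1), 4)$logPost, -Inf)
  q2 <- tinyParams(T, S)
  q2$sigmaLe <- -1
  expect_identical(logPosterior(q2, fo, tinyObs(T, S, 1), 4)$logPost, -Inf)
})
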