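# Small in-code fixtures shared across test files.

# forcing table with a controllable temperature path
tinyForcing <- function(ST, SM = rep(25, length(ST)),
                        V = rep(10, length(ST))) {
  T <- length(ST)
  data.frame(year = 2011L + (seq_len(T) - 1L) %/% 36L,
             month = ((seq_len(T) - 1L) %/% 3L) %% 12L + 1L,
             tercile = (seq_len(T) - 1L) %% 3L + 1L,
             ST = ST, SM = SM, V = V)
}

# a small admissible parameter set over a given forcing
tinyParams <- function(T, S, seed = 1) {
  set.seed(seed)
  list(le = rnorm(T, -6, 0.3),
       betaSt = rnorm(T, 0.8, 0.1),
       betaSm = rnorm(T, 0.02, 0.005),
       gamma = 0.004, betaBase = 2e-4, b1 = 1.2,
       sigmaLe = 0.4, sigmaSt = 0.15, sigmaSm = 0.02,
       cvT = runif(T, 0.2, 0.5),
       cvS = matrix(runif(T * S, 0.2, 0.5), T, S),
       ps = matrix(rgamma(T * S, 5, 50), T, S))
}

# observations with some records missing
tinyObs <- function(T, S, C, seed = 2, dropFrac = 0.1) {
  set.seed(seed)
  obs <- expand.grid(t = seq_len(T), scanner = seq_len(S),
                     image = seq_len(C))
  obs$production <- rgamma(nrow(obs), 4, 40)
  obs <- obs[runif(nrow(obs)) >= dropFrac, , drop = FALSE]
  rownames(obs) <- NULL
  obs
}

# build a PosteriorDraws object from explicit path draws (draws x T
# matrices); p and beta are derived through the model math so that
# postprocessing consistency can be asserted against it
fakeFit <- function(le, bst, bsm, forcing, b = NULL, betaBase = 1e-4,
                    stmin = 4) {
  nd <- nrow(le); T <- ncol(le)
  if (is.null(b)) b <- matrix(1, nd, T)
  beta <- t(vapply(seq_len(nd), function(d)
    growthRate(le[d, ], bst[d, ], bsm[d, ], forcing$SM, forcing$ST,
               stmin, betaBase), numeric(T)))
  p <- beta * b
  blocks <- list(le = le, betaSt = bst, betaSm = bsm, b = b, p = p,
                 beta = beta)
  draws <- do.call(cbind, lapply(names(blocks), function(nm) {
    m <- blocks[[nm]]
    colnames(m) <- sprintf("%s[%d]", nm, seq_len(T))
    m
  }))
  draws <- cbind(draws, betaBase = rep(betaBase, nd),
                 gamma = rep(0.005, nd), b1 = b[, 1])
  new("PosteriorDraws", draws = draws,
      chain = rep(1L, nd),
      pointwiseLogLik = matrix(numeric(), nd, 0),
      obsKey = data.frame(t = integer(), scanner = integer(),
                          image = integer(), production = numeric()),
      stmin = stmin, mcmc = unclass(mcmcConfig(chains = 1,
                                               iterations = 2 * nd,
                                               warmup = nd,
                                               thinKeepFraction = 1)),
      rhat = numeric())
}

# a one-year synthetic study small enough for sampler smoke tests
smokeStudy <- function(seed = 11, years = 1, S = 2, C = 2) {
  makeSyntheticStudy(syntheticConfig(years = years, S = S, C = C,
                                     missingnessRate = 0.05, seed = seed))
}
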