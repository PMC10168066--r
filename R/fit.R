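#' @include likelihood.R AllClasses.R
NULL

#' MCMC configuration
#'
#' Defaults follow the study protocol: four parallel chains of 30,000
#' iterations each including a 10,000-iteration warmup, post-warmup draws
#' thinned to 20% (every 5th draw), giving exactly 16,000 retained draws,
#' and convergence flagged at split R-hat > 1.1.
#'
#' @param chains Number of chains (>= 2 for R-hat).
#' @param iterations Total iterations per chain, including warmup.
#' @param warmup Warmup iterations per chain (< iterations).
#' @param thinKeepFraction Fraction of post-warmup draws kept; every
#'   \code{round(1/thinKeepFraction)}-th draw is retained.
#' @param seed Integer seed; chain c uses \code{seed + c}.
#' @param rhatThreshold Convergence flag threshold.
#' @param adapt JAGS adaptation iterations (in addition to warmup).
#' @return Named list of class \code{"rootSSM_mcmc"}.
#' @examples
#' retainedDraws(mcmcConfig()) # 16000
#' @export
mcmcConfig <- function(chains = 4, iterations = 30000, warmup = 10000,
                       thinKeepFraction = 0.2, seed = 1,
                       rhatThreshold = 1.1, adapt = 500) {
  stopifnot(chains >= 1, warmup >= 0, warmup < iterations,
            thinKeepFraction > 0, thinKeepFraction <= 1)
  thin <- round(1 / thinKeepFraction)
  if ((iterations - warmup) %% thin != 0)
    stop("(iterations - warmup) must be divisible by round(1/thinKeepFraction)")
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup),
                 thinKeepFraction = thinKeepFraction,
                 thin = as.integer(thin), seed = as.integer(seed),
                 rhatThreshold = rhatThreshold,
                 adapt = as.integer(adapt)),
            class = "rootSSM_mcmc")
}

#' Retained draw count implied by an MCMC configuration
#'
#' @param mcmc A [mcmcConfig()].
#' @return \code{chains * (iterations - warmup) * thinKeepFraction}.
#' @export
retainedDraws <- function(mcmc) {
  as.integer(mcmc$chains * (mcmc$iterations - mcmc$warmup) / mcmc$thin)
}

# JAGS translation of the model. stmin enters through the data (above,
# logDiff), so the step function never meets the sampler. Dispersions are
# parameterised by coefficients of variation (shape = 1/cv^2), which keeps
# gamma shapes away from the spike at zero that stalls slice sampling.
.jagsModel <- function(censored) {
  paste0('
model {
  le[1] ~ dnorm(le1Mean, le1Prec)
  bst[1] ~ dnorm(0, coef1Prec)
  bsm[1] ~ dnorm(0, coef1Prec)
  for (t in 2:T) {
    le[t] ~ dnorm(le[t-1], tauLe)
    bst[t] ~ dnorm(bst[t-1], tauSt)
    bsm[t] ~ dnorm(bsm[t-1], tauSm)
  }
  sigmaLe ~ dnorm(0, sigmaPrec) T(sigmaLower,)
  sigmaSt ~ dnorm(0, sigmaPrec) T(sigmaLower,)
  sigmaSm ~ dnorm(0, sigmaPrec) T(sigmaLower,)
  tauLe <- 1 / (sigmaLe * sigmaLe)
  tauSt <- 1 / (sigmaSt * sigmaSt)
  tauSm <- 1 / (sigmaSm * sigmaSm)
  gamma ~ dnorm(0, gammaPrec) T(0, gammaUpper)
  betaBase ~ dnorm(0, betaBasePrec) T(betaBaseLower,)
  b1 ~ dnorm(b1Mean, b1Prec) T(0,)
  b[1] <- b1
  for (t in 2:T) {
    b[t] <- b[t-1] * (1 + (beta[t-1] - gamma) * V[t-1])
  }
  for (t in 1:T) {
    beta[t] <- above[t] * exp(le[t] + (bst[t] + bsm[t] * SM[t]) * logDiff[t]) + betaBase
    p[t] <- beta[t] * b[t]
    cvT[t] ~ dnorm(0, cvPrec) T(cvLower,)
    shT[t] <- 1 / (cvT[t] * cvT[t])
    for (s in 1:S) {
      ps[t,s] ~ dgamma(shT[t], shT[t] / p[t])
      cvS[t,s] ~ dnorm(0, cvPrec) T(cvLower,)
      shS[t,s] <- 1 / (cvS[t,s] * cvS[t,s])
    }
  }
  for (i in 1:N) {
    F[i] ~ dgamma(shS[tIdx[i], sIdx[i]], shS[tIdx[i], sIdx[i]] / ps[tIdx[i], sIdx[i]])
  }
', if (censored) '
  for (i in 1:N0) {
    Fcen[i] ~ dgamma(shS[t0Idx[i], s0Idx[i]], shS[t0Idx[i], s0Idx[i]] / ps[t0Idx[i], s0Idx[i]])
    isPos[i] ~ dinterval(Fcen[i], delta)
  }
' else '', '
}
')
}

# initial values: start the latent paths where the observed production
# profile puts them, jittered per chain
.jagsInits <- function(chain, dat, priors, mcmc, T, S) {
  set.seed(mcmc$seed * 1000L + chain)
  meanF <- mean(dat$F)
  bstI <- 0.5 + rnorm(1, 0, 0.05)
  bsmI <- 0.01 + rnorm(1, 0, 0.002)
  smm <- mean(dat$SM)
  # per-period observed mean production
  pbar <- rep(NA_real_, T)
  sums <- tapply(dat$F, dat$tIdx, mean)
  pbar[as.integer(names(sums))] <- sums
  pbar[is.na(pbar) | pbar <= 0] <- meanF
  # invert the growth-rate link at b ~ b1Mean for above-threshold periods
  leI <- log(pmax(pbar / priors$b1Mean, 1e-8)) -
    (bstI + bsmI * smm) * dat$logDiff
  leI[dat$above == 0] <- log(max(meanF / priors$b1Mean, 1e-8))
  leI <- as.numeric(stats::filter(leI, rep(1 / 3, 3), sides = 2))
  leI[is.na(leI)] <- leI[!is.na(leI)][c(1, sum(!is.na(leI)))]
  leI <- leI + rnorm(1, 0, 0.2)
  psI <- matrix(meanF, T, S)
  for (i in seq_len(dat$N))
    psI[dat$tIdx[i], dat$sIdx[i]] <- 0
  cnt <- matrix(0, T, S)
  for (i in seq_len(dat$N)) {
    psI[dat$tIdx[i], dat$sIdx[i]] <-
      psI[dat$tIdx[i], dat$sIdx[i]] + dat$F[i]
    cnt[dat$tIdx[i], dat$sIdx[i]] <- cnt[dat$tIdx[i], dat$sIdx[i]] + 1
  }
  psI <- ifelse(cnt > 0, psI / pmax(cnt, 1), meanF)
  psI <- pmax(psI, 1e-10)
  ini <- list(le = leI, bst = rep(bstI, T), bsm = rep(bsmI, T),
              sigmaLe = 0.3, sigmaSt = 0.1, sigmaSm = 0.02,
              gamma = 0.004, betaBase = 1e-4, b1 = priors$b1Mean,
              cvT = rep(0.3, T), cvS = matrix(0.3, T, S), ps = psI,
              .RNG.name = "base::Mersenne-Twister",
              .RNG.seed = mcmc$seed * 1000L + chain)
  if (!is.null(dat$N0)) ini$Fcen <- rep(dat$delta / 2, dat$N0)
  ini
}

#' Fit the state-space model at a fixed temperature threshold
#'
#' Posterior sampling of the latent coefficient paths, scalar parameters,
#' dispersions and scanner-level means, by MCMC (JAGS) targeting the same
#' joint density as [logPosterior()]. The threshold \code{stmin} is fixed
#' (select it with [gridSearchStmin()]); zero production records are
#' treated as left-censored at the prior's \code{delta}. Returns thinned,
#' merged draws with the per-draw observation-level log-likelihood (for
#' [computeWaic()]) and split R-hat per parameter.
#'
#' @param rse A [RootScanExperiment-class].
#' @param stmin Fixed minimum-temperature threshold, degC.
#' @param priors A [priorConfig()].
#' @param mcmc A [mcmcConfig()].
#' @param quiet Suppress JAGS progress output.
#' @return A [PosteriorDraws-class].
#' @export
fitStateSpace <- function(rse, stmin, priors = priorConfig(),
                          mcmc = mcmcConfig(), quiet = TRUE) {
  forcing <- as.data.frame(rowData(rse))
  obs <- observationTable(rse)
  T <- nrow(forcing)
  scanners <- sort(unique(colData(rse)$scanner))
  S <- length(scanners)
  sIdxAll <- match(obs$scanner, scanners)
  above <- as.numeric(forcing$ST > stmin + priors$eps)
  logDiff <- ifelse(above == 1, log(pmax(forcing$ST - stmin, 1e-12)), 0)
  zero <- obs$production == 0
  delta <- priors$delta
  if (is.null(delta)) {
    pos <- obs$production[!zero]
    delta <- if (length(pos)) min(pos) / 2 else .Machine$double.eps
  }
  dat <- list(T = T, S = S, SM = forcing$SM, V = forcing$V,
              above = above, logDiff = logDiff,
              F = obs$production[!zero], tIdx = obs$t[!zero],
              sIdx = sIdxAll[!zero], N = sum(!zero),
              le1Mean = priors$le1Mean, le1Prec = 1 / priors$le1Sd^2,
              coef1Prec = 1 / priors$coef1Sd^2,
              sigmaPrec = 1 / priors$sigmaSd^2,
              sigmaLower = priors$sigmaLower,
              gammaPrec = 1 / priors$gammaSd^2,
              gammaUpper = min(priors$gammaUpper,
                               0.99 / max(forcing$V)),
              betaBasePrec = 1 / priors$betaBaseSd^2,
              betaBaseLower = priors$betaBaseLower,
              b1Mean = priors$b1Mean,
              b1Prec = 1 / (priors$b1RelSd * priors$b1Mean)^2,
              cvPrec = 1 / priors$cvSd^2, cvLower = priors$cvLower)
  censored <- any(zero)
  if (censored) {
    if (priors$zeroRule == "offset") {
      dat$F <- c(dat$F, rep(delta, sum(zero)))
      dat$tIdx <- c(dat$tIdx, obs$t[zero])
      dat$sIdx <- c(dat$sIdx, sIdxAll[zero])
      dat$N <- length(dat$F)
      censored <- FALSE
    } else {
      dat$N0 <- sum(zero)
      dat$t0Idx <- obs$t[zero]
      dat$s0Idx <- sIdxAll[zero]
      dat$delta <- delta
      dat$isPos <- rep(0L, sum(zero)) # observed below delta
    }
  }
  inits <- lapply(seq_len(mcmc$chains), .jagsInits, dat = dat,
                  priors = priors, mcmc = mcmc, T = T, S = S)
  jm <- rjags::jags.model(textConnection(.jagsModel(censored)), data = dat,
                          inits = inits, n.chains = mcmc$chains,
                          n.adapt = mcmc$adapt, quiet = quiet)
  pb <- if (quiet) "none" else "text"
  update(jm, mcmc$warmup, progress.bar = pb)
  monitors <- c("le", "bst", "bsm", "gamma", "betaBase", "b1",
                "sigmaLe", "sigmaSt", "sigmaSm", "cvT", "cvS", "ps",
                "b", "p", "beta")
  sm <- rjags::coda.samples(jm, monitors,
                            n.iter = mcmc$iterations - mcmc$warmup,
                            thin = mcmc$thin, progress.bar = pb)
  rhat <- if (mcmc$chains >= 2L) computeRhat(sm)
          else rep(NA_real_, ncol(as.matrix(sm[[1]])))
  draws <- do.call(rbind, lapply(sm, as.matrix))
  colnames(draws) <- sub("^bst", "betaSt",
                         sub("^bsm", "betaSm", colnames(draws)))
  names(rhat) <- colnames(draws)
  chain <- rep(seq_len(mcmc$chains), each = nrow(draws) / mcmc$chains)
  obsKey <- data.frame(t = obs$t, scanner = obs$scanner,
                       image = obs$image, production = obs$production)
  pw <- .pointwiseFromDraws(draws, obsKey, sIdxAll, T, S, delta,
                            priors$zeroRule)
  lw <- .latentFromDraws(draws, T, S)
  fit <- new("PosteriorDraws", draws = draws, chain = as.integer(chain),
             pointwiseLogLik = pw, latentLogLik = lw, obsKey = obsKey,
             stmin = stmin, mcmc = unclass(mcmc), rhat = rhat)
  nbad <- sum(rhat > mcmc$rhatThreshold, na.rm = TRUE)
  if (nbad > 0)
    warning(sprintf("%d parameter(s) with split R-hat > %.2f (max %.3f)",
                    nbad, mcmc$rhatThreshold, max(rhat, na.rm = TRUE)))
  fit
}

# observation-level log-likelihood per draw, from monitored ps and cvS
.pointwiseFromDraws <- function(draws, obsKey, sIdx, T, S, delta,
                                zeroRule) {
  n <- nrow(obsKey)
  pw <- matrix(NA_real_, nrow(draws), n)
  for (i in seq_len(n)) {
    j <- sprintf("[%d,%d]", obsKey$t[i], sIdx[i])
    sh <- 1 / draws[, paste0("cvS", j)]^2
    rate <- sh / draws[, paste0("ps", j)]
    F <- obsKey$production[i]
    if (F == 0) {
      if (zeroRule == "censor")
        pw[, i] <- pgamma(delta, shape = sh, rate = rate, log.p = TRUE)
      else
        pw[, i] <- dgamma(delta, shape = sh, rate = rate, log = TRUE)
    } else {
      pw[, i] <- dgamma(F, shape = sh, rate = rate, log = TRUE)
    }
  }
  pw
}

# scanner-level latent-mean log densities per draw: ps_{t,s} under
# Gamma(shape_t, shape_t / p_t); one column per (t, s) cell
.latentFromDraws <- function(draws, T, S) {
  lw <- matrix(NA_real_, nrow(draws), T * S)
  cn <- character(T * S)
  k <- 0L
  for (s in seq_len(S)) for (t in seq_len(T)) {
    k <- k + 1L
    cell <- sprintf("[%d,%d]", t, s)
    sh <- 1 / draws[, paste0("cvT[", t, "]")]^2
    lw[, k] <- dgamma(draws[, paste0("ps", cell)], shape = sh,
                      rate = sh / draws[, paste0("p[", t, "]")],
                      log = TRUE)
    cn[k] <- paste0("ps", cell)
  }
  colnames(lw) <- cn
  lw
}
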