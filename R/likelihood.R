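#' @include model-math.R
#' @importFrom stats dnorm pnorm dgamma pgamma rnorm rgamma rpois rbinom
#'   quantile var sd median cor rexp runif
NULL

#' Prior configuration for the state-space model
#'
#' Weakly informative defaults. All positive parameters use truncated
#' normal priors; dispersions are parameterised by the per-period (and
#' per-scanner) coefficient of variation \code{cv} of the gamma levels,
#' from which the rate is derived as \code{lambda = 1 / (cv^2 * mean)}.
#'
#' @param gammaSd Half-normal sd of the mortality rate, day-1.
#' @param gammaUpper Upper truncation of the mortality rate; the default
#'   0.09 day-1 keeps the mass-balance multiplier \code{1+(beta-gamma)V}
#'   positive for every dekad length (V <= 11 d) and is far beyond any
#'   biologically plausible turnover.
#' @param betaBaseSd Half-normal sd of the baseline growth rate, day-1.
#' @param sigmaSd Half-normal sd of the random-walk standard deviations.
#' @param cvSd Half-normal sd of the gamma-level coefficients of
#'   variation. The default keeps replicate CVs mostly below ~60%, i.e.
#'   gamma shapes of order one or larger: scanner images disagreeing by
#'   more than half their value would contradict the measurement design,
#'   and small-shape gamma levels both stall slice samplers and let the
#'   hierarchy absorb system-model misfit, degrading model comparison.
#' @param cvLower Lower truncation of the cv parameters (guards against a
#'   degenerate zero-variance observation model).
#' @param b1Mean Prior mean of the initial standing root area, mm2 cm-2;
#'   set this to the standing root area traced on the first image when
#'   available.
#' @param b1RelSd Prior sd of b1 as a fraction of \code{b1Mean}.
#' @param le1Mean,le1Sd Normal initialisation prior of the latent
#'   other-factor path.
#' @param coef1Sd Normal(0, coef1Sd) initialisation prior of the two
#'   temperature coefficient paths.
#' @param eps Threshold guard, degC (see [growthRate()]).
#' @param zeroRule How zero production records enter the likelihood:
#'   \code{"censor"} treats them as left-censored at \code{delta} (gamma
#'   CDF), \code{"offset"} adds \code{delta} to them.
#' @param delta Censoring/offset constant; \code{NULL} = half the smallest
#'   positive observed production.
#' @return A named list of class \code{"rootSSM_priors"}.
#' @export
priorConfig <- function(gammaSd = 0.05, gammaUpper = 0.09,
                        betaBaseSd = 0.01, betaBaseLower = 1e-8,
                        sigmaSd = 1, sigmaLower = 1e-4, cvSd = 0.25,
                        cvLower = 0.01, b1Mean = 1, b1RelSd = 0.5,
                        le1Mean = -5, le1Sd = 5, coef1Sd = 1,
                        eps = .DEFAULT_EPS,
                        zeroRule = c("censor", "offset"), delta = NULL) {
  zeroRule <- match.arg(zeroRule)
  stopifnot(gammaSd > 0, gammaUpper > 0, betaBaseSd > 0, sigmaSd > 0,
            cvSd > 0, cvLower >= 0, b1Mean > 0, b1RelSd > 0, le1Sd > 0,
            coef1Sd > 0, eps > 0, betaBaseLower >= 0, sigmaLower >= 0)
  structure(list(
    gammaSd = gammaSd, gammaUpper = gammaUpper, betaBaseSd = betaBaseSd,
    betaBaseLower = betaBaseLower, sigmaSd = sigmaSd,
    sigmaLower = sigmaLower, cvSd = cvSd, cvLower = cvLower,
    b1Mean = b1Mean, b1RelSd = b1RelSd, le1Mean = le1Mean, le1Sd = le1Sd,
    coef1Sd = coef1Sd, eps = eps, zeroRule = zeroRule, delta = delta),
    class = "rootSSM_priors")
}

# log density of Normal(mu, sd) truncated to (lower, upper)
.dtnorm <- function(x, mu, sd, lower = 0, upper = Inf) {
  Z <- pnorm(upper, mu, sd) - pnorm(lower, mu, sd)
  ifelse(x > lower & x < upper | (is.infinite(upper) & x >= lower),
         dnorm(x, mu, sd, log = TRUE) - log(Z), -Inf)
}

#' Hierarchical gamma observation log-likelihood
#'
#' Two error levels: scanner means
#' \eqn{ps_{t,s} \sim Gamma(\lambda_t p_t, \lambda_t)} (mean \eqn{p_t}) and
#' image-level observations
#' \eqn{F_{t,s,c} \sim Gamma(\lambda s_{t,s}\, ps_{t,s}, \lambda s_{t,s})}
#' (mean \eqn{ps_{t,s}}). Missing (t, s, c) records contribute nothing.
#' Zero-valued records are treated as left-censored at \code{delta}
#' (default) or shifted by it.
#'
#' @param obs Long observation data.frame with columns \code{t},
#'   \code{scanner}, \code{production} (see [observationTable()]).
#' @param ps T x S matrix of latent scanner-level means; > 0.
#' @param lambdaT length-T vector of scanner-level rates; > 0.
#' @param lambdaS T x S matrix of image-level rates; > 0.
#' @param p length-T mean production path; > 0.
#' @param delta Censoring/offset constant for zero records; \code{NULL} =
#'   half the smallest positive production in \code{obs}.
#' @param zeroRule \code{"censor"} or \code{"offset"}.
#' @return List with \code{pointwise} (one term per row of \code{obs}),
#'   \code{scannerLevel} (T x S matrix of latent-mean densities) and
#'   \code{total}.
#' @export
hierGammaLogLik <- function(obs, ps, lambdaT, lambdaS, p, delta = NULL,
                            zeroRule = c("censor", "offset")) {
  zeroRule <- match.arg(zeroRule)
  T <- length(p)
  stopifnot(nrow(ps) == T, identical(dim(ps), dim(lambdaS)),
            length(lambdaT) == T)
  if (any(p <= 0) || any(ps <= 0) || any(lambdaT <= 0) || any(lambdaS <= 0))
    stop("hierGammaLogLik: gamma shapes/rates must be strictly positive")
  scannerLevel <- dgamma(ps, shape = lambdaT * p, rate = lambdaT,
                         log = TRUE)
  pointwise <- numeric(nrow(obs))
  if (nrow(obs)) {
    ij <- cbind(obs$t, obs$scanner)
    shape <- lambdaS[ij] * ps[ij]
    rate <- lambdaS[ij]
    F <- obs$production
    if (is.null(delta)) {
      pos <- F[F > 0]
      delta <- if (length(pos)) min(pos) / 2 else .Machine$double.eps
    }
    if (zeroRule == "offset") F <- ifelse(F == 0, delta, F)
    zero <- F == 0
    pointwise[!zero] <- dgamma(F[!zero], shape = shape[!zero],
                               rate = rate[!zero], log = TRUE)
    if (any(zero))
      pointwise[zero] <- pgamma(delta, shape = shape[zero],
                                rate = rate[zero], log.p = TRUE)
  }
  list(pointwise = pointwise, scannerLevel = scannerLevel,
       total = sum(pointwise) + sum(scannerLevel))
}

#' Gaussian random-walk log prior of a coefficient path
#'
#' Sum over steps of \eqn{Normal(path_t \mid path_{t-1}, \sigma^2)}
#' log-densities, plus an optional normal initialisation prior on the first
#' element (flat if omitted).
#'
#' @param path Numeric vector, length >= 2.
#' @param sigma Step standard deviation; > 0.
#' @param initMean,initSd Initialisation prior on \code{path[1]};
#'   \code{NULL} = flat.
#' @return Scalar log density.
#' @examples
#' randomWalkLogPrior(c(0, 1), 1) # standard normal log-density at 1
#' @export
randomWalkLogPrior <- function(path, sigma, initMean = NULL, initSd = NULL) {
  stopifnot(length(path) >= 2, sigma > 0)
  lp <- sum(dnorm(diff(path), 0, sigma, log = TRUE))
  if (!is.null(initMean))
    lp <- lp + dnorm(path[1], initMean, initSd, log = TRUE)
  lp
}

# rates from cv parameterisation: lambda = 1/(cv^2 * mean)
.ratesFromCv <- function(cvT, cvS, p, ps) {
  list(lambdaT = 1 / (cvT^2 * p), lambdaS = 1 / (cvS^2 * ps))
}

#' Joint log posterior of the state-space model
#'
#' Composes the deterministic trajectory, the hierarchical gamma
#' likelihood, the three random-walk priors and the scalar-parameter
#' priors at a fixed temperature threshold. Parameter combinations that
#' violate the mass-balance positivity constraint (or any support bound)
#' return \code{-Inf} rather than an error, so samplers can reject them.
#'
#' @param params Named list: paths \code{le}, \code{betaSt}, \code{betaSm}
#'   (length T); scalars \code{gamma}, \code{betaBase}, \code{b1},
#'   \code{sigmaLe}, \code{sigmaSt}, \code{sigmaSm}; dispersions \code{cvT}
#'   (length T), \code{cvS} (T x S) and latent means \code{ps} (T x S).
#' @param forcing Dekadal forcing data.frame.
#' @param obs Long observation data.frame (t, scanner, image, production).
#' @param stmin Fixed temperature threshold, degC (selected by
#'   [gridSearchStmin()], not sampled).
#' @param priors A [priorConfig()].
#' @return List with \code{logPost}, the observation-level \code{pointwise}
#'   log-likelihood vector (for WAIC), \code{logLik} (both gamma levels)
#'   and \code{logPrior}.
#' @export
logPosterior <- function(params, forcing, obs, stmin,
                         priors = priorConfig()) {
  pr <- priors
  T <- nrow(forcing)
  S <- ncol(params$ps)
  reject <- list(logPost = -Inf, pointwise = NULL, logLik = -Inf,
                 logPrior = -Inf)
  q <- params
  if (q$gamma <= 0 || q$gamma >= pr$gammaUpper ||
      q$betaBase < pr$betaBaseLower || q$b1 <= 0 ||
      q$sigmaLe <= pr$sigmaLower || q$sigmaSt <= pr$sigmaLower ||
      q$sigmaSm <= pr$sigmaLower ||
      any(q$cvT <= pr$cvLower) || any(q$cvS <= pr$cvLower) ||
      any(q$ps <= 0))
    return(reject)
  scal <- new("ScalarParams", b1 = q$b1, gamma = q$gamma,
              betaBase = q$betaBase, stmin = stmin, sigmaLe = q$sigmaLe,
              sigmaSt = q$sigmaSt, sigmaSm = q$sigmaSm)
  traj <- tryCatch(
    biomassTrajectory(forcing, q$le, q$betaSt, q$betaSm, scal,
                      eps = pr$eps),
    rootSSM_positivity = function(e) NULL)
  if (is.null(traj) || any(traj@p <= 0)) return(reject)
  rates <- .ratesFromCv(q$cvT, q$cvS, traj@p, q$ps)
  ll <- hierGammaLogLik(obs, q$ps, rates$lambdaT, rates$lambdaS, traj@p,
                        delta = pr$delta, zeroRule = pr$zeroRule)
  lp <- randomWalkLogPrior(q$le, q$sigmaLe, pr$le1Mean, pr$le1Sd) +
    randomWalkLogPrior(q$betaSt, q$sigmaSt, 0, pr$coef1Sd) +
    randomWalkLogPrior(q$betaSm, q$sigmaSm, 0, pr$coef1Sd) +
    .dtnorm(q$gamma, 0, pr$gammaSd, 0, pr$gammaUpper) +
    .dtnorm(q$betaBase, 0, pr$betaBaseSd, pr$betaBaseLower) +
    .dtnorm(q$b1, pr$b1Mean, pr$b1RelSd * pr$b1Mean) +
    .dtnorm(q$sigmaLe, 0, pr$sigmaSd, pr$sigmaLower) +
    .dtnorm(q$sigmaSt, 0, pr$sigmaSd, pr$sigmaLower) +
    .dtnorm(q$sigmaSm, 0, pr$sigmaSd, pr$sigmaLower) +
    sum(.dtnorm(q$cvT, 0, pr$cvSd, pr$cvLower)) +
    sum(.dtnorm(q$cvS, 0, pr$cvSd, pr$cvLower))
  list(logPost = ll$total + lp, pointwise = ll$pointwise,
       logLik = ll$total, logPrior = lp)
}
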