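#' @include model-math.R preprocess.R
#' @importFrom stats aggregate
NULL

#' Configuration of a synthetic root-production study
#'
#' Bundles everything needed to simulate a complete study: seasonal
#' forcing, ground-truth model parameters and coefficient paths, the
#' two-level gamma observation noise, and missingness. Defaults emulate a
#' temperate-forest site (winter soil temperature minima of roughly
#' 1-6 degC, summer maxima of 25-28 degC, episodic soil moisture pulses
#' between about 12% and 40%) and a quasi-steady-state root system: with
#' \code{le0 = "auto"} the latent other-factor baseline is calibrated by
#' bisection so standing root area is annually balanced (production
#' integral matches mortality), which keeps trajectories realistic instead
#' of exponentially exploding or dying out.
#'
#' @param years Number of complete calendar years (>= 1).
#' @param S Scanners (>= 1).
#' @param C Depth-wise images per scanner (>= 1).
#' @param scalars Ground-truth [ScalarParams-class].
#' @param startYear First calendar year of the series.
#' @param tempMean,tempAmp,tempPhase,tempNoiseSd Daily soil temperature
#'   sinusoid: mean (degC), seasonal amplitude (degC), phase (day of year
#'   of the upward zero crossing) and daily noise sd.
#' @param smBase,smEventRate,smEventMag,smDecay Daily soil moisture:
#'   baseline (%), Poisson precipitation-event rate (events/day), mean
#'   pulse magnitude (%), exponential decay rate (day-1); clipped to
#'   [0, 100].
#' @param cvScanner,cvImage Coefficients of variation of the scanner-level
#'   and image-level gamma noise (rates are derived as
#'   \code{1/(cv^2 * mean)}).
#' @param missingnessRate Probability that a (t, s, c) record is missing,
#'   completely at random (in [0, 1)).
#' @param pathSpec \code{"smooth"} (seasonal sinusoids), \code{"random_walk"}
#'   (the model's own prior), or \code{"fixed"} (user paths via
#'   \code{fixedPaths}).
#' @param bstMid,bstAmp,bstPhase Smooth temperature-coefficient path
#'   \code{bstMid + bstAmp * sin(2*pi*(doy - bstPhase)/365)} (default range
#'   0.5-1.5, peaking in spring).
#' @param bsmMid,bsmAmp,bsmPhase Smooth interaction-coefficient path
#'   (default range 0-0.06).
#' @param le0 Latent other-factor baseline (log scale), or \code{"auto"}.
#' @param leAmp Seasonal amplitude of the latent other-factor path.
#' @param fixedPaths For \code{pathSpec = "fixed"}: list with \code{le},
#'   \code{betaSt}, \code{betaSm}, each of length T.
#' @param seed Integer seed; every stochastic stage derives its stream
#'   from it.
#' @return Named list of class \code{"rootSSM_synth_config"}.
#' @export
syntheticConfig <- function(years = 2, S = 3, C = 4,
                            scalars = scalarParams(
                              b1 = 1, gamma = 0.005, betaBase = 1e-4,
                              stmin = 4, sigmaLe = 0.5, sigmaSt = 0.2,
                              sigmaSm = 0.02),
                            startYear = 2011,
                            tempMean = 15.5, tempAmp = 12,
                            tempPhase = 110, tempNoiseSd = 1.2,
                            smBase = 12, smEventRate = 0.12,
                            smEventMag = 8, smDecay = 0.08,
                            cvScanner = 0.3, cvImage = 0.3,
                            missingnessRate = 0.05,
                            pathSpec = c("smooth", "random_walk", "fixed"),
                            bstMid = 1.0, bstAmp = 0.5, bstPhase = 30,
                            bsmMid = 0.03, bsmAmp = 0.03, bsmPhase = 35,
                            le0 = "auto", leAmp = 0,
                            fixedPaths = NULL, seed = 1) {
  pathSpec <- match.arg(pathSpec)
  if (years < 1 || S < 1 || C < 1) stop("years, S and C must be >= 1")
  if (missingnessRate < 0 || missingnessRate >= 1)
    stop("missingnessRate must be in [0, 1)")
  structure(as.list(environment()), class = "rootSSM_synth_config")
}

#' Generate daily and dekadal synthetic forcing
#'
#' Daily soil temperature is a seasonal sinusoid plus Gaussian noise;
#' daily soil moisture is a baseline plus exponentially decaying pulses at
#' Poisson event times, clipped to [0, 100]. Dekadal values are the
#' arithmetic means of the daily values ([aggregateToDekads()]).
#'
#' @param config A [syntheticConfig()].
#' @return List with \code{daily} (date, soil_temp_c, soil_moist_pct) and
#'   \code{forcing} (dekadal).
#' @export
generateForcing <- function(config) {
  cf <- config
  set.seed(cf$seed)
  start <- as.Date(sprintf("%d-01-01", cf$startYear))
  end <- as.Date(sprintf("%d-12-31", cf$startYear + cf$years - 1L))
  dates <- seq(start, end, by = "1 day")
  n <- length(dates)
  doy <- as.POSIXlt(dates)$yday + 1
  st <- cf$tempMean +
    cf$tempAmp * sin(2 * pi * (doy - cf$tempPhase) / 365) +
    (if (cf$tempNoiseSd > 0) rnorm(n, 0, cf$tempNoiseSd) else 0)
  nev <- rpois(n, cf$smEventRate)
  sm <- rep(cf$smBase, n)
  for (i in which(nev > 0)) {
    amp <- sum(rexp(nev[i], 1 / cf$smEventMag))
    idx <- i:n
    sm[idx] <- sm[idx] + amp * exp(-cf$smDecay * (idx - i))
  }
  sm <- pmin(pmax(sm, 0), 100)
  daily <- data.frame(date = dates, soil_temp_c = st, soil_moist_pct = sm)
  list(daily = daily, forcing = aggregateToDekads(daily))
}

# mid-period day of year for smooth path evaluation
.dekadDoy <- function(forcing) {
  start <- as.Date(sprintf("%04d-%02d-%02d", forcing$year, forcing$month,
                           c(1L, 11L, 21L)[forcing$tercile]))
  as.POSIXlt(start + forcing$V / 2)$yday + 1
}

# bisection on the le-path offset so that log(b_T / b_1) ~ 0
.calibrateLe <- function(forcing, leShape, betaSt, betaSm, scalars,
                         lo = -25, hi = 5, tol = 1e-8) {
  f <- function(le0) {
    traj <- tryCatch(
      biomassTrajectory(forcing, leShape + le0, betaSt, betaSm, scalars),
      rootSSM_positivity = function(e) NULL)
    if (is.null(traj)) return(Inf) # exploded upward
    log(traj@b[length(traj@b)] / traj@b[1])
  }
  # growth is monotone in le0: f(lo) < 0 < f(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Simulate ground-truth latent coefficient paths and their trajectory
#'
#' Draws (or accepts) the three coefficient paths and runs the
#' deterministic mass-balance recursion. Random-walk draws violating the
#' positivity constraint are rejected and redrawn (with a message).
#'
#' @param forcing Dekadal forcing data.frame.
#' @param scalars Ground-truth [ScalarParams-class].
#' @param config A [syntheticConfig()] (path shape parameters are read
#'   from it).
#' @param seed Integer seed.
#' @return A [LatentTrajectory-class].
#' @export
simulateLatent <- function(forcing, scalars, config, seed = 1) {
  cf <- config
  T <- nrow(forcing)
  doy <- .dekadDoy(forcing)
  set.seed(seed)
  if (cf$pathSpec == "fixed") {
    fp <- cf$fixedPaths
    if (is.null(fp) || length(fp$le) != T || length(fp$betaSt) != T ||
        length(fp$betaSm) != T)
      stop("fixedPaths must supply le, betaSt, betaSm of length T = ", T)
    return(biomassTrajectory(forcing, fp$le, fp$betaSt, fp$betaSm,
                             scalars))
  }
  for (try in 1:100) {
    if (cf$pathSpec == "smooth") {
      betaSt <- cf$bstMid +
        cf$bstAmp * sin(2 * pi * (doy - cf$bstPhase) / 365)
      betaSm <- cf$bsmMid +
        cf$bsmAmp * sin(2 * pi * (doy - cf$bsmPhase) / 365)
      leShape <- cf$leAmp * sin(2 * pi * (doy - cf$bstPhase) / 365)
    } else { # random_walk
      betaSt <- cumsum(c(cf$bstMid, rnorm(T - 1, 0, scalars@sigmaSt)))
      betaSm <- cumsum(c(cf$bsmMid, rnorm(T - 1, 0, scalars@sigmaSm)))
      leShape <- cumsum(c(0, rnorm(T - 1, 0, scalars@sigmaLe)))
    }
    le0 <- if (identical(cf$le0, "auto"))
      .calibrateLe(forcing, leShape, betaSt, betaSm, scalars)
    else cf$le0
    traj <- tryCatch(
      biomassTrajectory(forcing, leShape + le0, betaSt, betaSm, scalars),
      rootSSM_positivity = function(e) NULL)
    if (!is.null(traj)) return(traj)
    message("latent draw ", try, " violated positivity; redrawing")
  }
  stop("no admissible latent trajectory in 100 draws")
}

#' Simulate hierarchical gamma observations
#'
#' Per period and scanner, a latent scanner mean
#' \eqn{ps_{t,s} \sim Gamma(\lambda_t p_t, \lambda_t)}; per image an
#' observation \eqn{F_{t,s,c} \sim Gamma(\lambda s\, ps_{t,s}, \lambda s)}.
#' Records are then dropped independently at \code{missingnessRate}.
#' Dispersions may be given directly as rates (\code{lambdaT},
#' \code{lambdaS}) or as coefficients of variation (\code{cvScanner},
#' \code{cvImage}), from which rates are derived.
#'
#' @param truth A [LatentTrajectory-class].
#' @param S,C Scanner and image counts.
#' @param lambdaT length-T vector or scalar rate; or \code{NULL} to use
#'   \code{cvScanner}.
#' @param lambdaS T x S matrix or scalar rate; or \code{NULL} to use
#'   \code{cvImage}.
#' @param cvScanner,cvImage Coefficients of variation (used when the
#'   corresponding rate is \code{NULL}).
#' @param missingnessRate Per-record missingness probability.
#' @param seed Integer seed.
#' @return List with \code{observations} (long data.frame: t, scanner,
#'   image, production) and \code{dispersion}
#'   ([DispersionParams-class], including the drawn \code{ps}).
#' @export
simulateObservations <- function(truth, S, C, lambdaT = NULL,
                                 lambdaS = NULL, cvScanner = 0.3,
                                 cvImage = 0.3, missingnessRate = 0,
                                 seed = 1) {
  p <- truth@p
  T <- length(p)
  set.seed(seed)
  if (is.null(lambdaT)) lambdaT <- 1 / (cvScanner^2 * p)
  lambdaT <- rep_len(lambdaT, T)
  ps <- matrix(rgamma(T * S, shape = rep(lambdaT * p, S),
                      rate = rep(lambdaT, S)), T, S)
  if (is.null(lambdaS)) lambdaS <- 1 / (cvImage^2 * ps)
  if (!is.matrix(lambdaS)) lambdaS <- matrix(lambdaS, T, S)
  F <- array(rgamma(T * S * C, shape = rep(as.vector(lambdaS * ps), C),
                    rate = rep(as.vector(lambdaS), C)), c(T, S, C))
  obs <- data.frame(t = rep(seq_len(T), S * C),
                    scanner = rep(rep(seq_len(S), each = T), C),
                    image = rep(seq_len(C), each = T * S),
                    production = as.vector(F))
  if (missingnessRate > 0)
    obs <- obs[runif(nrow(obs)) >= missingnessRate, , drop = FALSE]
  obs <- obs[order(obs$t, obs$scanner, obs$image), , drop = FALSE]
  rownames(obs) <- NULL
  list(observations = obs,
       dispersion = new("DispersionParams", lambdaT = lambdaT,
                        lambdaS = lambdaS, ps = ps))
}

#' Generate a complete synthetic study
#'
#' Composes [generateForcing()], [simulateLatent()] and
#' [simulateObservations()] into a [SyntheticStudy-class] whose truth is
#' stored alongside the data for parameter-recovery scoring. Bit-for-bit
#' reproducible from the config seed (sub-stages use seed, seed + 1,
#' seed + 2).
#'
#' @param config A [syntheticConfig()].
#' @return A [SyntheticStudy-class].
#' @examples
#' study <- makeSyntheticStudy(syntheticConfig(years = 1, S = 2, C = 2))
#' study
#' @export
makeSyntheticStudy <- function(config) {
  cf <- config
  fo <- generateForcing(cf)
  truth <- simulateLatent(fo$forcing, cf$scalars, cf, seed = cf$seed + 1L)
  so <- simulateObservations(truth, cf$S, cf$C,
                             cvScanner = cf$cvScanner,
                             cvImage = cf$cvImage,
                             missingnessRate = cf$missingnessRate,
                             seed = cf$seed + 2L)
  rse <- alignDataset(fo$forcing, so$observations, trim = FALSE)
  new("SyntheticStudy", daily = fo$daily, forcing = fo$forcing,
      truth = truth, dispersion = so$dispersion,
      observations = so$observations, experiment = rse,
      config = unclass(cf))
}

#' Write a synthetic study to CSV files
#'
#' Daily forcing, dekadal forcing, long observations, a truth CSV with the
#' latent paths, and a JSON manifest.
#'
#' @param study A [SyntheticStudy-class].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
writeSyntheticStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(study@daily, file.path(dir, "forcing_daily.csv"),
            row.names = FALSE)
  writeForcingCSV(study@forcing, file.path(dir, "forcing_dekadal.csv"))
  writeProductionCSV(study@observations,
                     file.path(dir, "production_dekadal.csv"))
  tr <- study@truth
  truthDf <- data.frame(t = seq_along(tr@le), le = tr@le,
                        betaSt = tr@betaSt, betaSm = tr@betaSm,
                        b = tr@b, p = tr@p)
  write.csv(truthDf, file.path(dir, "truth_latent.csv"), row.names = FALSE)
  s <- tr@scalars
  manifest <- list(
    seed = study@config$seed, years = study@config$years,
    S = study@config$S, C = study@config$C,
    truth = list(b1 = s@b1, gamma = s@gamma, betaBase = s@betaBase,
                 stmin = s@stmin))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
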