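#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData
NULL

#' Scalar parameters of the root production state-space model
#'
#' Container for the time-constant parameters of the system model: the
#' initial standing root area \eqn{b_1} (mm2 cm-2), the constant mortality
#' rate \eqn{\gamma} (day-1), the baseline growth rate \eqn{\beta_{base}}
#' (day-1) that persists through the dormant season, the minimum soil
#' temperature threshold \eqn{st_{min}} (degC) below which the exogenous
#' response is switched off, and the random-walk standard deviations of the
#' three time-varying coefficient paths.
#'
#' @slot b1 numeric(1), initial standing root area, mm2 cm-2; > 0.
#' @slot gamma numeric(1), mortality rate, day-1; >= 0.
#' @slot betaBase numeric(1), baseline growth rate, day-1; >= 0.
#' @slot stmin numeric(1), minimum temperature threshold, degC.
#' @slot sigmaLe,sigmaSt,sigmaSm numeric(1), random-walk innovation standard
#'   deviations (per dekadal step) of the latent other-factor path and the
#'   temperature and temperature-moisture coefficient paths; > 0.
#' @seealso [scalarParams()]
#' @export
setClass("ScalarParams",
  representation(
    b1 = "numeric", gamma = "numeric", betaBase = "numeric",
    stmin = "numeric", sigmaLe = "numeric", sigmaSt = "numeric",
    sigmaSm = "numeric"
  )
)

setValidity("ScalarParams", function(object) {
  msg <- character()
  for (sl in c("b1", "gamma", "betaBase", "stmin",
               "sigmaLe", "sigmaSt", "sigmaSm")) {
    v <- slot(object, sl)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", sl))
  }
  if (length(msg)) return(msg)
  if (object@b1 <= 0) msg <- c(msg, "b1 must be > 0")
  if (object@gamma < 0) msg <- c(msg, "gamma must be >= 0")
  if (object@betaBase < 0) msg <- c(msg, "betaBase must be >= 0")
  for (sl in c("sigmaLe", "sigmaSt", "sigmaSm"))
    if (slot(object, sl) <= 0) msg <- c(msg, sprintf("%s must be > 0", sl))
  if (length(msg)) msg else TRUE
})

#' Construct a ScalarParams object
#'
#' @param b1 Initial standing root area, mm2 cm-2.
#' @param gamma Mortality rate, day-1.
#' @param betaBase Baseline growth rate, day-1.
#' @param stmin Minimum temperature threshold, degC.
#' @param sigmaLe,sigmaSt,sigmaSm Random-walk standard deviations.
#' @return A [ScalarParams-class] object.
#' @examples
#' scalarParams(b1 = 1, gamma = 0.005, betaBase = 1e-4, stmin = 4)
#' @export
scalarParams <- function(b1 = 1, gamma = 0.005, betaBase = 1e-4, stmin = 4,
                         sigmaLe = 0.5, sigmaSt = 0.2, sigmaSm = 0.02) {
  new("ScalarParams", b1 = b1, gamma = gamma, betaBase = betaBase,
      stmin = stmin, sigmaLe = sigmaLe, sigmaSt = sigmaSt, sigmaSm = sigmaSm)
}

#' Latent trajectory of the state-space system model
#'
#' Holds one realisation of the latent coefficient paths together with the
#' standing root area and mean production series they deterministically
#' imply through the mass-balance recursion
#' \eqn{b_t = b_{t-1} + p_{t-1} V_{t-1} - \gamma b_{t-1} V_{t-1}} and
#' \eqn{p_t = \beta_t b_t}.
#'
#' @slot le numeric(T), latent other-factor path (log scale).
#' @slot betaSt numeric(T), independent soil temperature effect path.
#' @slot betaSm numeric(T), temperature-moisture interaction path.
#' @slot b numeric(T), standing root area, mm2 cm-2; > 0.
#' @slot p numeric(T), mean fine root production, mm2 cm-2 day-1.
#' @slot scalars [ScalarParams-class].
#' @seealso [biomassTrajectory()]
#' @export
setClass("LatentTrajectory",
  representation(
    le = "numeric", betaSt = "numeric", betaSm = "numeric",
    b = "numeric", p = "numeric", scalars = "ScalarParams"
  )
)

setValidity("LatentTrajectory", function(object) {
  msg <- character()
  T <- length(object@le)
  if (T < 2L) msg <- c(msg, "paths must have length >= 2")
  for (sl in c("betaSt", "betaSm", "b", "p"))
    if (length(slot(object, sl)) != T)
      msg <- c(msg, sprintf("'%s' must have the same length as 'le'", sl))
  if (length(msg)) return(msg)
  if (any(!is.finite(object@b)) || any(object@b <= 0))
    msg <- c(msg, "standing root area b must be finite and > 0 everywhere")
  if (any(!is.finite(object@p)) || any(object@p < 0))
    msg <- c(msg, "production p must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' Dispersion parameters of the hierarchical gamma observation model
#'
#' Scanner-level rates \eqn{\lambda_t} (so that scanner means are
#' \eqn{ps_{t,s} \sim Gamma(\lambda_t p_t, \lambda_t)}), image-level rates
#' \eqn{\lambda s_{t,s}}, and the scanner-level latent means \eqn{ps_{t,s}}.
#'
#' @slot lambdaT numeric(T), scanner-level gamma rate per period; > 0.
#' @slot lambdaS matrix (T x S), image-level gamma rate per period and
#'   scanner; > 0.
#' @slot ps matrix (T x S), latent scanner-level mean production,
#'   mm2 cm-2 day-1; > 0.
#' @export
setClass("DispersionParams",
  representation(lambdaT = "numeric", lambdaS = "matrix", ps = "matrix")
)

setValidity("DispersionParams", function(object) {
  msg <- character()
  T <- length(object@lambdaT)
  if (nrow(object@lambdaS) != T || nrow(object@ps) != T)
    msg <- c(msg, "lambdaS and ps must have T rows")
  if (!identical(dim(object@lambdaS), dim(object@ps)))
    msg <- c(msg, "lambdaS and ps must have identical dimensions")
  if (length(msg)) return(msg)
  if (any(object@lambdaT <= 0) || any(object@lambdaS <= 0) ||
      any(object@ps <= 0))
    msg <- c(msg, "all dispersion parameters must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' Dekadal scanner experiment container
#'
#' The central data container: a \link[SummarizedExperiment]{SummarizedExperiment}
#' whose single assay \code{"production"} is the T x (S*C) matrix of observed
#' fine root production (mm2 cm-2 day-1; \code{NA} marks missing records),
#' with the dekadal environmental forcing (soil temperature \code{ST} degC,
#' soil moisture \code{SM} %, interval length \code{V} days, and the
#' year/month/tercile time index) as \code{rowData} and the scanner and
#' depth-wise image indices as \code{colData}.
#'
#' @seealso [RootScanExperiment()], [alignDataset()]
#' @export
setClass("RootScanExperiment", contains = "SummarizedExperiment")

setValidity("RootScanExperiment", function(object) {
  msg <- character()
  if (!"production" %in% names(assays(object)))
    msg <- c(msg, "assay 'production' is required")
  rd <- rowData(object)
  need <- c("year", "month", "tercile", "ST", "SM", "V")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste("rowData lacks:", paste(miss, collapse = ", ")))
  cd <- colData(object)
  miss <- setdiff(c("scanner", "image"), colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("colData lacks:", paste(miss, collapse = ", ")))
  if (length(msg)) return(msg)
  if (nrow(object) < 2L) msg <- c(msg, "need at least 2 periods")
  if (any(!is.finite(rd$V)) || any(rd$V <= 0))
    msg <- c(msg, "interval lengths V must be positive")
  if (!all(rd$tercile %in% 1:3))
    msg <- c(msg, "tercile must be in 1:3")
  pr <- assay(object, "production")
  if (any(pr[!is.na(pr)] < 0))
    msg <- c(msg, "production must be >= 0 where observed")
  if (anyDuplicated(paste(cd$scanner, cd$image)))
    msg <- c(msg, "(scanner, image) columns must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a RootScanExperiment
#'
#' @param production Numeric matrix, T periods x (scanner,image) columns,
#'   \code{NA} for missing records.
#' @param forcing Dekadal forcing data.frame with columns \code{year},
#'   \code{month}, \code{tercile}, \code{ST}, \code{SM}, \code{V} (see
#'   [aggregateToDekads()]).
#' @param scanner,image Integer vectors, one entry per column of
#'   \code{production}.
#' @return A [RootScanExperiment-class].
#' @export
RootScanExperiment <- function(production, forcing, scanner, image) {
  stopifnot(nrow(production) == nrow(forcing),
            ncol(production) == length(scanner),
            length(scanner) == length(image))
  rd <- DataFrame(forcing)
  rownames(production) <- dekadLabel(forcing)
  colnames(production) <- sprintf("s%d.c%d", scanner, image)
  se <- SummarizedExperiment(
    assays = list(production = production),
    rowData = rd,
    colData = DataFrame(scanner = as.integer(scanner),
                        image = as.integer(image),
                        row.names = colnames(production))
  )
  new("RootScanExperiment", se)
}

#' Posterior draws from the state-space model fit
#'
#' Thinned, merged MCMC draws with chain bookkeeping, the per-draw
#' pointwise observation log-likelihood needed for WAIC, and split R-hat
#' per monitored parameter.
#'
#' @slot draws numeric matrix, n_draws x n_params, named columns
#'   (coda-style, e.g. \code{"betaSt[12]"}).
#' @slot chain integer vector of length n_draws giving the chain of origin.
#' @slot pointwiseLogLik numeric matrix, n_draws x n_obs, observation-level
#'   log-likelihood contributions.
#' @slot latentLogLik numeric matrix, n_draws x (T*S), scanner-level
#'   latent-mean log-density contributions (used by the conditional WAIC;
#'   see [computeWaic()]).
#' @slot obsKey data.frame with one row per observation (columns \code{t},
#'   \code{scanner}, \code{image}, \code{production}).
#' @slot stmin numeric(1), the fixed threshold this fit was run at.
#' @slot mcmc list, the [mcmcConfig()] used.
#' @slot rhat named numeric, split R-hat per parameter.
#' @export
setClass("PosteriorDraws",
  representation(
    draws = "matrix", chain = "integer", pointwiseLogLik = "matrix",
    latentLogLik = "matrix", obsKey = "data.frame", stmin = "numeric",
    mcmc = "list", rhat = "numeric"
  ),
  prototype(latentLogLik = matrix(numeric(), 0, 0))
)

setValidity("PosteriorDraws", function(object) {
  msg <- character()
  if (is.null(colnames(object@draws)))
    msg <- c(msg, "draws must have column names")
  if (length(object@chain) != nrow(object@draws))
    msg <- c(msg, "chain must have one entry per draw")
  if (nrow(object@pointwiseLogLik) &&
      nrow(object@pointwiseLogLik) != nrow(object@draws))
    msg <- c(msg, "pointwiseLogLik must have one row per draw")
  if (ncol(object@pointwiseLogLik) != nrow(object@obsKey))
    msg <- c(msg, "pointwiseLogLik must have one column per observation")
  if (length(msg)) msg else TRUE
})

#' WAIC decomposition
#'
#' Widely applicable information criterion computed from pointwise
#' posterior log-likelihoods: \code{waic = -2 * (lppd - pWaic)}.
#'
#' @slot lppd numeric(1), log pointwise predictive density.
#' @slot pWaic numeric(1), effective number of parameters (variance form).
#' @slot waic numeric(1).
#' @slot pointwise data.frame with per-observation \code{lppd} and
#'   \code{pWaic} contributions.
#' @export
setClass("WaicResult",
  representation(lppd = "numeric", pWaic = "numeric", waic = "numeric",
                 pointwise = "data.frame")
)

setValidity("WaicResult", function(object) {
  msg <- character()
  if (object@pWaic < 0) msg <- c(msg, "pWaic must be >= 0")
  d <- object@waic - (-2 * (object@lppd - object@pWaic))
  if (is.finite(d) && abs(d) > 1e-8)
    msg <- c(msg, "waic must equal -2*(lppd - pWaic)")
  if (length(msg)) msg else TRUE
})

#' Synthetic study bundle
#'
#' A complete simulated dataset: daily and dekadal forcing, the ground-truth
#' latent trajectory and dispersion parameters, the simulated observations,
#' and the assembled [RootScanExperiment-class].
#'
#' @slot daily data.frame of daily forcing (date, soil_temp_c,
#'   soil_moist_pct).
#' @slot forcing dekadal forcing data.frame.
#' @slot truth [LatentTrajectory-class] ground truth.
#' @slot dispersion [DispersionParams-class] ground truth.
#' @slot observations long data.frame (t, scanner, image, production).
#' @slot experiment [RootScanExperiment-class].
#' @slot config list, the [syntheticConfig()] used (includes the seed).
#' @export
setClass("SyntheticStudy",
  representation(
    daily = "data.frame", forcing = "data.frame",
    truth = "LatentTrajectory", dispersion = "DispersionParams",
    observations = "data.frame", experiment = "RootScanExperiment",
    config = "list"
  )
)
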