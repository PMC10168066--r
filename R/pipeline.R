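#' @include synthetic.R fit.R gridsearch.R effects.R
#' @importFrom tools md5sum
NULL

#' Read a pipeline run configuration
#'
#' YAML file with blocks \code{paths} (forcing, production, outputDir),
#' \code{stand} (name, exclusionDays), \code{priors}, \code{mcmc},
#' \code{grid} (lo, hi, step) and \code{seed}; every block is optional and
#' falls back to package defaults. Command functions
#' ([runSimulate()], [runFit()], [runScanStmin()], [runReport()]) take
#' either a path or the list this returns.
#'
#' @param path YAML file path.
#' @return Named list of class \code{"rootSSM_runconfig"}.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "rootSSM_runconfig")
}

.asRunConfig <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  config
}

.configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(config[sort(names(config))]), f)
  unname(tools::md5sum(f))
}

.cfgSeed <- function(config) {
  if (is.null(config$seed)) stop("config must set a seed")
  as.integer(config$seed)
}

.cfgMcmc <- function(config) {
  m <- as.list(config$mcmc)
  if (is.null(m$seed)) m$seed <- .cfgSeed(config)
  do.call(mcmcConfig, m)
}

.cfgPriors <- function(config) do.call(priorConfig, as.list(config$priors))

.writeManifest <- function(dir, config, extra = list()) {
  manifest <- c(list(configHash = .configHash(unclass(config)),
                     seed = config$seed,
                     timestamp = format(Sys.time(), tz = "UTC")), extra)
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Pipeline stage: simulate a synthetic study to disk
#'
#' @param config Run configuration (list or YAML path); the
#'   \code{synthetic} block is passed to [syntheticConfig()].
#' @return The output directory, invisibly.
#' @export
runSimulate <- function(config) {
  config <- .asRunConfig(config)
  dir <- config$paths$outputDir %||% "rootssm_out"
  sc <- do.call(syntheticConfig,
                c(config$synthetic, list(seed = .cfgSeed(config))))
  study <- makeSyntheticStudy(sc)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSyntheticStudy(study, dir)
  .writeManifest(dir, config, list(stage = "simulate"))
  invisible(dir)
}

# assemble the model-ready experiment from the configured input files
.loadDataset <- function(config) {
  p <- config$paths
  stopifnot(!is.null(p$forcing), !is.null(p$production))
  forcing <- if (grepl("daily", p$forcing))
    aggregateToDekads(readDailyForcingCSV(p$forcing))
  else readForcingCSV(p$forcing)
  hdr <- names(read.csv(p$production, nrows = 1))
  if ("scan_date" %in% hdr) {
    raw <- readRawProductionCSV(p$production)
    excl <- config$stand$exclusionDays
    if (!is.null(excl))
      raw <- excludeDisturbanceWindow(raw, unlist(excl))
    obs <- assignProductionToDekads(raw)
  } else {
    obs <- readProductionCSV(p$production)
  }
  alignDataset(forcing, obs, trim = is.null(config$trim) || config$trim)
}

#' Pipeline stage: fit at a fixed threshold and write summaries
#'
#' Preprocesses the configured inputs, fits the state-space model at
#' \code{config$stmin}, and writes posterior summaries, the R-hat report,
#' WAIC and a manifest into the output directory. Parameters exceeding
#' the R-hat threshold are listed in a warning.
#'
#' @param config Run configuration (list or YAML path).
#' @return The [PosteriorDraws-class], invisibly; files as side effect.
#' @export
runFit <- function(config) {
  config <- .asRunConfig(config)
  dir <- config$paths$outputDir %||% "rootssm_out"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rse <- .loadDataset(config)
  stmin <- config$stmin %||% 4
  fit <- fitStateSpace(rse, stmin, priors = .cfgPriors(config),
                       mcmc = .cfgMcmc(config))
  write.csv(summarizePosterior(fit), file.path(dir, "posterior_summary.csv"),
            row.names = FALSE)
  rh <- rhatValues(fit)
  write.csv(data.frame(parameter = names(rh), rhat = rh),
            file.path(dir, "rhat_report.csv"), row.names = FALSE)
  w <- computeWaic(fit)
  writeStudyBundle(rse, file.path(dir, "dataset"))
  .writeManifest(dir, config, list(stage = "fit", stmin = stmin,
                                   waic = w@waic,
                                   maxRhat = max(rh, na.rm = TRUE),
                                   draws = nrow(fit@draws)))
  saveDrawsCSV(fit, file.path(dir, "draws"))
  invisible(fit)
}

#' Pipeline stage: threshold grid scan
#'
#' @param config Run configuration; the \code{grid} block gives
#'   \code{lo}, \code{hi}, \code{step}.
#' @return The [gridSearchStmin()] result, invisibly; writes
#'   \code{waic_profile.csv} and \code{best_stmin.json}.
#' @export
runScanStmin <- function(config) {
  config <- .asRunConfig(config)
  dir <- config$paths$outputDir %||% "rootssm_out"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rse <- .loadDataset(config)
  g <- config$grid %||% list()
  scan <- gridSearchStmin(rse, gridLo = g$lo %||% 0, gridHi = g$hi %||% 10,
                          step = g$step %||% 0.1,
                          priors = .cfgPriors(config),
                          mcmc = .cfgMcmc(config),
                          cores = config$cores %||% 1)
  write.csv(scan$profile, file.path(dir, "waic_profile.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(bestStmin = scan$bestStmin,
         note = "ties break toward the lower threshold"),
    file.path(dir, "best_stmin.json"), auto_unbox = TRUE)
  .writeManifest(dir, config, list(stage = "scan-stmin",
                                   bestStmin = scan$bestStmin))
  invisible(scan)
}

#' Pipeline stage: derived-effect report from saved draws
#'
#' Loads draws written by [runFit()] (refusing a manifest whose config
#' hash differs), and writes the effect series, regression curves and
#' production report tables and plots.
#'
#' @param config Run configuration.
#' @return Invisibly, the list of tables written.
#' @export
runReport <- function(config) {
  config <- .asRunConfig(config)
  dir <- config$paths$outputDir %||% "rootssm_out"
  man <- jsonlite::read_json(file.path(dir, "run_manifest.json"))
  if (!identical(man$configHash, .configHash(unclass(config))))
    stop("draws manifest hash does not match this configuration")
  fit <- loadDrawsCSV(file.path(dir, "draws"))
  rse <- readStudyBundle(file.path(dir, "dataset"))
  forcing <- forcingData(rse)
  es <- effectSeries(fit, forcing)
  rc <- regressionCurves(fit, forcing)
  rep <- productionReport(fit, rse)
  write.csv(es, file.path(dir, "effect_series.csv"), row.names = FALSE)
  write.csv(rc, file.path(dir, "regression_curves.csv"),
            row.names = FALSE)
  write.csv(rep$table, file.path(dir, "production_summary.csv"),
            row.names = FALSE)
  write.csv(rep$peaks, file.path(dir, "production_peaks.csv"),
            row.names = FALSE)
  ggplot2::ggsave(file.path(dir, "production_bands.pdf"),
                  plotProduction(rep), width = 9, height = 4)
  ggplot2::ggsave(file.path(dir, "effect_series.pdf"),
                  plotEffectSeries(es), width = 9, height = 4)
  ggplot2::ggsave(file.path(dir, "regression_curves.pdf"),
                  plotRegressionCurves(rc, stmin = fit@stmin),
                  width = 6, height = 5)
  invisible(list(effects = es, curves = rc, production = rep))
}

#' Persist posterior draws as columnar text
#'
#' Draws, chain index, pointwise log-likelihood and a JSON manifest
#' (parameter names, chains, seed, stmin), readable by [loadDrawsCSV()].
#'
#' @param fit A [PosteriorDraws-class].
#' @param dir Directory.
#' @return The directory, invisibly.
#' @export
saveDrawsCSV <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dr <- as.data.frame(fit@draws, check.names = FALSE)
  dr$`.chain` <- fit@chain
  write.csv(dr, file.path(dir, "draws.csv"), row.names = FALSE)
  write.csv(as.data.frame(fit@pointwiseLogLik),
            file.path(dir, "pointwise_loglik.csv"), row.names = FALSE)
  write.csv(as.data.frame(fit@latentLogLik),
            file.path(dir, "latent_loglik.csv"), row.names = FALSE)
  write.csv(fit@obsKey, file.path(dir, "obs_key.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(stmin = fit@stmin, mcmc = fit@mcmc,
         rhat = as.list(fit@rhat)),
    file.path(dir, "draws_manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname saveDrawsCSV
#' @export
loadDrawsCSV <- function(dir) {
  dr <- read.csv(file.path(dir, "draws.csv"), check.names = FALSE)
  chain <- as.integer(dr$`.chain`)
  dr$`.chain` <- NULL
  pw <- as.matrix(read.csv(file.path(dir, "pointwise_loglik.csv")))
  lf <- file.path(dir, "latent_loglik.csv")
  lw <- if (file.exists(lf)) as.matrix(read.csv(lf))
        else matrix(numeric(), 0, 0)
  obsKey <- read.csv(file.path(dir, "obs_key.csv"))
  man <- jsonlite::read_json(file.path(dir, "draws_manifest.json"),
                             simplifyVector = TRUE)
  new("PosteriorDraws", draws = as.matrix(dr), chain = chain,
      pointwiseLogLik = pw, latentLogLik = lw, obsKey = obsKey,
      stmin = man$stmin, mcmc = as.list(man$mcmc), rhat = unlist(man$rhat))
}

#' Print the default configuration blocks
#'
#' @return Invisibly, the list of defaults; printed as YAML.
#' @export
showConfig <- function() {
  defaults <- list(
    seed = 1,
    stmin = 4,
    paths = list(forcing = "forcing_dekadal.csv",
                 production = "production_dekadal.csv",
                 outputDir = "rootssm_out"),
    stand = list(name = "oak", exclusionDays = list(cypress = 307,
                                                    oak = 68)),
    priors = unclass(priorConfig()),
    mcmc = unclass(mcmcConfig())[c("chains", "iterations", "warmup",
                                   "thinKeepFraction", "rhatThreshold",
                                   "adapt")],
    grid = list(lo = 0, hi = 10, step = 0.1),
    synthetic = list(years = 2, S = 3, C = 4))
  cat(yaml::as.yaml(defaults))
  invisible(defaults)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
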