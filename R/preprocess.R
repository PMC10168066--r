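#' @include AllClasses.R
#' @importFrom utils read.csv write.csv
NULL

# days in month, leap-aware, vectorised
.daysInMonth <- function(year, month) {
  ny <- ifelse(month == 12L, year + 1L, year)
  nm <- ifelse(month == 12L, 1L, month + 1L)
  as.integer(as.Date(sprintf("%d-%02d-01", ny, nm)) -
               as.Date(sprintf("%d-%02d-01", year, month)))
}

#' Dekad (early/mid/late of month) of calendar dates
#'
#' Dekads split each month into days 1-10, 11-20, and 21 to month end,
#' giving 36 periods per year.
#'
#' @param dates A Date vector.
#' @return data.frame with columns \code{year}, \code{month},
#'   \code{tercile} (1 = early, 2 = mid, 3 = late).
#' @export
dekadOfDate <- function(dates) {
  dates <- as.Date(dates)
  lt <- as.POSIXlt(dates)
  day <- lt$mday
  data.frame(year = lt$year + 1900L, month = lt$mon + 1L,
             tercile = ifelse(day <= 10, 1L, ifelse(day <= 20, 2L, 3L)))
}

#' Label dekadal periods
#'
#' @param forcing data.frame with \code{year}, \code{month}, \code{tercile}.
#' @return Character labels like \code{"2011-04-mid"}.
#' @export
dekadLabel <- function(forcing) {
  sprintf("%04d-%02d-%s", forcing$year, forcing$month,
          c("early", "mid", "late")[forcing$tercile])
}

#' Dekadal calendar between two dates
#'
#' @param startDate,endDate Dates (inclusive); the calendar covers every
#'   dekad touched by the range.
#' @return data.frame with \code{year}, \code{month}, \code{tercile},
#'   \code{V} (calendar length in days, in \{8, 9, 10, 11\}),
#'   \code{start}, \code{end} (Dates).
#' @examples
#' cal <- dekadCalendar(as.Date("2013-01-01"), as.Date("2013-12-31"))
#' nrow(cal)  # 36
#' sum(cal$V) # 365
#' @export
dekadCalendar <- function(startDate, endDate) {
  startDate <- as.Date(startDate); endDate <- as.Date(endDate)
  stopifnot(startDate <= endDate)
  s <- dekadOfDate(startDate); e <- dekadOfDate(endDate)
  months <- seq(as.Date(sprintf("%d-%02d-01", s$year, s$month)),
                as.Date(sprintf("%d-%02d-01", e$year, e$month)),
                by = "1 month")
  lt <- as.POSIXlt(months)
  out <- data.frame(year = rep(lt$year + 1900L, each = 3L),
                    month = rep(lt$mon + 1L, each = 3L),
                    tercile = rep(1:3, length(months)))
  dim <- .daysInMonth(out$year, out$month)
  out$V <- ifelse(out$tercile < 3L, 10L, dim - 20L)
  out$start <- as.Date(sprintf("%04d-%02d-%02d", out$year, out$month,
                               c(1L, 11L, 21L)[out$tercile]))
  out$end <- out$start + out$V - 1L
  keep <- out$end >= startDate & out$start <= endDate
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate daily sensor series to dekadal means
#'
#' Arithmetic mean of the available daily values within each dekad;
#' \code{V} is the calendar length of the dekad regardless of coverage.
#' Dekads with no coverage get \code{NA} values (flagged missing, never
#' imputed).
#'
#' @param daily data.frame with a \code{date} column and the daily value
#'   columns \code{soil_temp_c} and \code{soil_moist_pct}.
#' @param minCoverage Minimum fraction of days per calendar year that must
#'   be present; below it an error is raised.
#' @return Dekadal forcing data.frame (\code{year}, \code{month},
#'   \code{tercile}, \code{ST}, \code{SM}, \code{V}).
#' @export
aggregateToDekads <- function(daily, minCoverage = 0.5) {
  stopifnot(all(c("date", "soil_temp_c", "soil_moist_pct") %in%
                  names(daily)))
  daily$date <- as.Date(daily$date)
  if (anyDuplicated(daily$date)) stop("duplicate dates in daily series")
  yr <- as.POSIXlt(daily$date)$year + 1900L
  for (y in unique(yr)) {
    nd <- 365 + (.daysInMonth(y, 2L) == 29L)
    cov <- sum(yr == y) / nd
    if (cov < minCoverage)
      stop(sprintf("year %d has %.0f%% daily coverage (< %.0f%%)",
                   y, 100 * cov, 100 * minCoverage))
  }
  cal <- dekadCalendar(min(daily$date), max(daily$date))
  key <- dekadLabel(dekadOfDate(daily$date))
  calKey <- dekadLabel(cal)
  idx <- match(key, calKey)
  agg <- function(v) {
    m <- tapply(v, factor(idx, levels = seq_len(nrow(cal))),
                mean, na.rm = TRUE)
    as.numeric(m)
  }
  out <- data.frame(year = cal$year, month = cal$month,
                    tercile = cal$tercile,
                    ST = agg(daily$soil_temp_c),
                    SM = agg(daily$soil_moist_pct), V = cal$V)
  out$ST[is.nan(out$ST)] <- NA_real_
  out$SM[is.nan(out$SM)] <- NA_real_
  out
}

#' Attribute scan-interval production rates to dekads
#'
#' Each scan reports a mean production rate over the interval since the
#' previous scan of the same (scanner, image). The rate is attributed to
#' the dekads the interval overlaps, weighted by the number of overlapping
#' days, and the weighted mean rate per (dekad, scanner, image) is
#' returned. This conserves time-integrated production. Dekads with no
#' scan coverage are absent (missing), never zero.
#'
#' @param raw data.frame with columns \code{scan_date}, \code{scanner_id},
#'   \code{image_id}, \code{production_mm2_cm2_d}, \code{installation_date}
#'   (per scanner; starts the first interval).
#' @param maxGapDays Scan gaps longer than this raise a warning (the rate
#'   is still attributed).
#' @return Long data.frame (\code{year}, \code{month}, \code{tercile},
#'   \code{scanner}, \code{image}, \code{production}).
#' @export
assignProductionToDekads <- function(raw, maxGapDays = 45) {
  need <- c("scan_date", "scanner_id", "image_id", "production_mm2_cm2_d",
            "installation_date")
  stopifnot(all(need %in% names(raw)))
  raw$scan_date <- as.Date(raw$scan_date)
  raw$installation_date <- as.Date(raw$installation_date)
  pieces <- list()
  for (grp in split(raw, list(raw$scanner_id, raw$image_id), drop = TRUE)) {
    grp <- grp[order(grp$scan_date), , drop = FALSE]
    prev <- c(grp$installation_date[1], grp$scan_date[-nrow(grp)])
    len <- as.integer(grp$scan_date - prev)
    if (any(len > maxGapDays))
      warning(sprintf("scan gap of %d days for scanner %s image %s",
                      max(len), grp$scanner_id[1], grp$image_id[1]))
    if (any(len <= 0)) stop("scan dates must strictly increase per image")
    # interval i covers days prev+1 .. scan_date
    days <- as.Date(unlist(mapply(
      function(a, b) as.list(seq(a + 1L, b, by = "1 day")),
      prev, grp$scan_date, SIMPLIFY = FALSE), use.names = FALSE),
      origin = "1970-01-01")
    dk <- dekadOfDate(days)
    # every day of an interval carries its rate, so the per-dekad mean of
    # daily rates equals the overlap-weighted mean over intervals
    dk$rate <- rep(grp$production_mm2_cm2_d, times = len)
    m <- aggregate(rate ~ year + month + tercile, data = dk, FUN = mean)
    w <- aggregate(rate ~ year + month + tercile, data = dk, FUN = length)
    pieces[[length(pieces) + 1L]] <- data.frame(
      year = m$year, month = m$month, tercile = m$tercile,
      scanner = grp$scanner_id[1], image = grp$image_id[1],
      production = m$rate, weight = w$rate)
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$year, out$month, out$tercile, out$scanner,
                   out$image), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop records inside the post-installation disturbance window
#'
#' Scanner installation disturbs the surrounding soil; fine root dynamics
#' are unstable for a stand-specific period afterwards (defaults: 307 days
#' for the cypress stand, 68 for the oak stand). Records scanned at most
#' \code{exclusionDays} after installation are removed.
#'
#' @param raw Raw production data.frame (see
#'   [assignProductionToDekads()]), optionally with a \code{stand} column.
#' @param exclusionDays Named vector of days per stand, or a single number
#'   applied to all records.
#' @return The filtered data.frame; the number of dropped records is
#'   reported via \code{message()}.
#' @export
excludeDisturbanceWindow <- function(raw,
                                     exclusionDays = c(cypress = 307,
                                                       oak = 68)) {
  stopifnot(all(exclusionDays >= 0))
  age <- as.numeric(as.Date(raw$scan_date) -
                      as.Date(raw$installation_date))
  if (length(exclusionDays) == 1L && is.null(names(exclusionDays))) {
    lim <- rep(exclusionDays, nrow(raw))
  } else {
    if (!"stand" %in% names(raw))
      stop("named exclusionDays require a 'stand' column")
    lim <- exclusionDays[as.character(raw$stand)]
    if (any(is.na(lim))) stop("stand without an exclusionDays entry")
  }
  drop <- age <= lim
  message(sum(drop), " record(s) inside the disturbance window dropped")
  out <- raw[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Align forcing and observations into a model-ready experiment
#'
#' Trims forcing and observations to their common dekadal range,
#' re-indexes periods, and assembles the [RootScanExperiment-class].
#'
#' @param forcing Dekadal forcing data.frame.
#' @param obs Long observation data.frame keyed either by period index
#'   \code{t} (into \code{forcing} rows) or by (\code{year}, \code{month},
#'   \code{tercile}).
#' @param trim Trim forcing to the observed period range (default). With
#'   \code{FALSE} the full forcing range is kept and only observations
#'   outside it are an error.
#' @return A [RootScanExperiment-class].
#' @export
alignDataset <- function(forcing, obs, trim = TRUE) {
  stopifnot(nrow(forcing) >= 2, nrow(obs) >= 1)
  if (!"t" %in% names(obs)) {
    key <- dekadLabel(obs)
    t <- match(key, dekadLabel(forcing))
    if (all(is.na(t))) stop("forcing and observation ranges are disjoint")
    if (any(is.na(t))) {
      obs <- obs[!is.na(t), , drop = FALSE]
      t <- t[!is.na(t)]
    }
    obs$t <- t
  }
  if (any(obs$t < 1 | obs$t > nrow(forcing)))
    stop("observation period index outside the forcing range")
  if (trim) {
    lo <- min(obs$t); hi <- max(obs$t)
    if (hi - lo < 1L) stop("common period range has fewer than 2 periods")
    forcing <- forcing[lo:hi, , drop = FALSE]
    obs$t <- obs$t - lo + 1L
  }
  if (any(is.na(forcing$ST)) || any(is.na(forcing$SM)))
    stop("forcing has missing dekads inside the model range")
  combos <- unique(obs[, c("scanner", "image")])
  combos <- combos[order(combos$scanner, combos$image), , drop = FALSE]
  prod <- matrix(NA_real_, nrow(forcing), nrow(combos))
  col <- match(paste(obs$scanner, obs$image),
               paste(combos$scanner, combos$image))
  if (anyDuplicated(cbind(obs$t, col)))
    stop("duplicate (period, scanner, image) records")
  prod[cbind(obs$t, col)] <- obs$production
  RootScanExperiment(prod, forcing[, c("year", "month", "tercile",
                                       "ST", "SM", "V")],
                     combos$scanner, combos$image)
}

#' Scanner image cropping geometry
#'
#' The analyzed soil-profile area per scan: a pair of depth-wise images,
#' each 5 cm wide by 20 cm deep (subdivided into four 5 cm squares for
#' tracing), giving 200 cm2 per scanner image.
#'
#' @param imageWidthCm,imageDepthCm Depth-wise image size, cm.
#' @param imagesPerScanner Depth-wise images cropped per scanned original.
#' @param subimagesPerImage Tracing subdivisions per depth-wise image.
#' @return List with the per-image and total analyzed areas (cm2).
#' @export
scanGeometry <- function(imageWidthCm = 5, imageDepthCm = 20,
                         imagesPerScanner = 2, subimagesPerImage = 4) {
  area <- imageWidthCm * imageDepthCm
  list(imageAreaCm2 = area,
       analyzedAreaCm2 = area * imagesPerScanner,
       subimageSizeCm = imageDepthCm / subimagesPerImage,
       imagesPerScanner = imagesPerScanner,
       subimagesPerImage = subimagesPerImage)
}

# ---- CSV schemas ----------------------------------------------------------

#' Read and write rootSSM CSV schemas
#'
#' Plain-CSV round-trip I/O: daily forcing (\code{date, soil_temp_c,
#' soil_moist_pct}), dekadal forcing (\code{year, month, tercile, ST, SM,
#' V}), dekadal long observations (\code{t, scanner, image, production})
#' and raw scan tables (\code{scan_date, scanner_id, image_id,
#' production_mm2_cm2_d, installation_date[, stand]}).
#'
#' @param path File path.
#' @param x Object to write.
#' @return The data.frame read, invisibly the path for writers.
#' @name rootssm-io
NULL

#' @rdname rootssm-io
#' @export
readDailyForcingCSV <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$date <- as.Date(d$date)
  d
}

#' @rdname rootssm-io
#' @export
writeForcingCSV <- function(x, path) {
  write.csv(x[, c("year", "month", "tercile", "ST", "SM", "V")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname rootssm-io
#' @export
readForcingCSV <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("year", "month", "tercile", "ST", "SM", "V") %in%
                  names(d)))
  d
}

#' @rdname rootssm-io
#' @export
writeProductionCSV <- function(x, path) {
  write.csv(x[, c("t", "scanner", "image", "production")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname rootssm-io
#' @export
readProductionCSV <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("t", "scanner", "image", "production") %in% names(d)))
  d
}

#' @rdname rootssm-io
#' @export
readRawProductionCSV <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$scan_date <- as.Date(d$scan_date)
  d$installation_date <- as.Date(d$installation_date)
  d
}

#' Serialize / load a model-ready study bundle
#'
#' Writes the experiment as paired CSVs (forcing + long observations) with
#' a JSON manifest (T, S, C, period labels), and reads it back exactly.
#'
#' @param rse A [RootScanExperiment-class].
#' @param dir Directory (created if needed).
#' @return \code{writeStudyBundle}: the directory, invisibly;
#'   \code{readStudyBundle}: the [RootScanExperiment-class].
#' @export
writeStudyBundle <- function(rse, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fo <- forcingData(rse)
  writeForcingCSV(fo, file.path(dir, "forcing_dekadal.csv"))
  writeProductionCSV(observationTable(rse),
                     file.path(dir, "production_dekadal.csv"))
  cd <- colData(rse)
  manifest <- list(T = nrow(rse),
                   S = length(unique(cd$scanner)),
                   C = length(unique(cd$image)),
                   periods = dekadLabel(fo))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname writeStudyBundle
#' @export
readStudyBundle <- function(dir) {
  forcing <- readForcingCSV(file.path(dir, "forcing_dekadal.csv"))
  obs <- readProductionCSV(file.path(dir, "production_dekadal.csv"))
  alignDataset(forcing, obs, trim = FALSE)
}
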