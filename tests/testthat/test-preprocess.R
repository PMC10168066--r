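test_that("dekad calendar arithmetic is exact", {
  jan <- dekadCalendar(as.Date("2013-01-01"), as.Date("2013-01-31"))
  expect_equal(jan$V, c(10, 10, 11))
  feb <- dekadCalendar(as.Date("2013-02-01"), as.Date("2013-02-28"))
  expect_equal(feb$V, c(10, 10, 8))
  feb16 <- dekadCalendar(as.Date("2016-02-01"), as.Date("2016-02-29"))
  expect_equal(feb16$V, c(10, 10, 9))
  yr <- dekadCalendar(as.Date("2013-01-01"), as.Date("2013-12-31"))
  expect_equal(nrow(yr), 36)
  expect_equal(sum(yr$V), 365)
  expect_true(all(yr$V %in% 8:11))
  leap <- dekadCalendar(as.Date("2016-01-01"), as.Date("2016-12-31"))
  expect_equal(sum(leap$V), 366)
})

test_that("daily aggregation averages within dekads and flags gaps", {
  dates <- seq(as.Date("2013-01-01"), as.Date("2013-12-31"), by = "1 day")
  daily <- data.frame(date = dates, soil_temp_c = 7.25,
                      soil_moist_pct = 31.5)
  fo <- aggregateToDekads(daily)
  expect_equal(nrow(fo), 36)
  expect_true(all(fo$ST == 7.25))
  expect_true(all(fo$SM == 31.5))
  # a fully missing dekad comes back NA, not imputed
  daily2 <- daily[!(dates >= as.Date("2013-05-11") &
                      dates <= as.Date("2013-05-20")), ]
  fo2 <- aggregateToDekads(daily2)
  expect_true(is.na(fo2$ST[fo2$month == 5 & fo2$tercile == 2]))
  expect_equal(fo2$V[fo2$month == 5 & fo2$tercile == 2], 10)
  # insufficient yearly coverage errors
  expect_error(aggregateToDekads(daily[1:100, ]), "coverage")
})

test_that("interval rates are attributed to dekads by overlap weighting", {
  # one interval exactly covering one dekad keeps its rate
  raw <- data.frame(scan_date = as.Date("2013-04-10"),
                    scanner_id = 1L, image_id = 1L,
                    production_mm2_cm2_d = 0.015,
                    installation_date = as.Date("2013-03-31"))
  out <- assignProductionToDekads(raw)
  expect_equal(nrow(out), 1)
  expect_equal(out$production, 0.015)
  expect_equal(out[, c("month", "tercile")],
               data.frame(month = 4L, tercile = 1L))
  # an interval spanning two dekads 6/4 contributes its rate to both,
  # with weights 6 and 4
  raw2 <- data.frame(scan_date = as.Date("2013-04-14"),
                     scanner_id = 1L, image_id = 1L,
                     production_mm2_cm2_d = 0.02,
                     installation_date = as.Date("2013-04-04"))
  out2 <- assignProductionToDekads(raw2)
  expect_equal(out2$production, c(0.02, 0.02))
  expect_equal(out2$weight, c(6, 4))
  # two intervals meeting inside a dekad: overlap-weighted mean
  raw3 <- data.frame(scan_date = as.Date(c("2013-04-06", "2013-04-10")),
                     scanner_id = 1L, image_id = 1L,
                     production_mm2_cm2_d = c(0.01, 0.03),
                     installation_date = as.Date("2013-04-01"))
  out3 <- assignProductionToDekads(raw3)
  expect_equal(out3$production, (5 * 0.01 + 4 * 0.03) / 9)
  # dekads without scans are absent, not zero
  expect_false(any(out3$production == 0))
  expect_equal(nrow(out3), 1)
})

test_that("aggregation conserves interval-weighted total production", {
  set.seed(41)
  scans <- sort(sample(5:120, 12))
  raw <- data.frame(scan_date = as.Date("2013-01-01") + scans,
                    scanner_id = 1L, image_id = 1L,
                    production_mm2_cm2_d = runif(12, 0, 0.03),
                    installation_date = as.Date("2013-01-01"))
  out <- assignProductionToDekads(raw)
  total <- sum(out$production * out$weight)
  lens <- diff(c(0, scans))
  expect_equal(total, sum(raw$production_mm2_cm2_d * lens),
               tolerance = 1e-9)
})

test_that("long scan gaps warn but are still attributed", {
  raw <- data.frame(scan_date = as.Date(c("2013-04-01", "2013-06-01")),
                    scanner_id = 1L, image_id = 1L,
                    production_mm2_cm2_d = 0.01,
                    installation_date = as.Date("2013-03-25"))
  expect_warning(assignProductionToDekads(raw), "gap")
})

test_that("disturbance-window exclusion drops early records per stand", {
  expect_message(
    out0 <- excludeDisturbanceWindow(
      data.frame(scan_date = as.Date("2013-01-10"),
                 installation_date = as.Date("2013-01-01")),
      exclusionDays = 0),
    "0 record")
  expect_equal(nrow(out0), 1) # identity filter at zero days
  days <- seq(30, 300, by = 30)
  raw <- data.frame(scan_date = as.Date("2012-01-01") + days,
                    scanner_id = 1L, image_id = 1L,
                    production_mm2_cm2_d = 0.01,
                    installation_date = as.Date("2012-01-01"),
                    stand = "oak")
  expected <- sum(days > 68) # brute-force count on the constructed table
  out <- suppressMessages(
    excludeDisturbanceWindow(raw, c(cypress = 307, oak = 68)))
  expect_equal(nrow(out), expected)
  rawC <- raw; rawC$stand <- "cypress"
  outC <- suppressMessages(excludeDisturbanceWindow(rawC))
  expect_equal(nrow(outC), sum(days > 307))
  expect_lte(nrow(outC), nrow(rawC)) # filtering never adds records
})

test_that("alignment trims to the common range and validates", {
  fo <- generateForcing(syntheticConfig(years = 1, seed = 6))$forcing
  obs <- tinyObs(36, 2, 2, seed = 3)
  rse <- alignDataset(fo, obs)
  expect_s4_class(rse, "RootScanExperiment")
  expect_equal(nrow(rse), 36)
  # observations starting late trim the forcing
  obsLate <- obs[obs$t >= 4, ]
  rseLate <- alignDataset(fo, obsLate)
  expect_equal(nrow(rseLate), 33)
  expect_equal(as.data.frame(rowData(rseLate))$ST, fo$ST[4:36])
  # label-keyed observations resolve through the calendar
  obsLbl <- cbind(fo[obs$t, c("year", "month", "tercile")],
                  obs[, c("scanner", "image", "production")])
  rseLbl <- alignDataset(fo, obsLbl)
  expect_equal(productionAssay(rseLbl), productionAssay(rse))
  # disjoint ranges error
  obsFar <- obsLbl
  obsFar$year <- obsFar$year + 10L
  expect_error(alignDataset(fo, obsFar), "disjoint")
})

test_that("scanner cropping geometry gives the analyzed area", {
  g <- scanGeometry()
  expect_equal(g$analyzedAreaCm2, 200)
  expect_equal(g$imageAreaCm2, 100)
})

test_that("CSV round-trips reproduce objects exactly", {
  st <- smokeStudy(seed = 17)
  f <- tempfile(fileext = ".csv")
  writeForcingCSV(st@forcing, f)
  fo2 <- readForcingCSV(f)
  expect_equal(fo2$ST, st@forcing$ST)
  expect_equal(fo2$V, st@forcing$V)
  p <- tempfile(fileext = ".csv")
  writeProductionCSV(st@observations, p)
  obs2 <- readProductionCSV(p)
  expect_equal(obs2$production, st@observations$production)
  expect_equal(obs2[, c("t", "scanner", "image")],
               st@observations[, c("t", "scanner", "image")])
  # full bundle round-trip preserves the experiment
  d <- tempfile()
  writeStudyBundle(st@experiment, d)
  rse2 <- readStudyBundle(d)
  expect_equal(productionAssay(rse2), productionAssay(st@experiment))
  expect_equal(as.data.frame(rowData(rse2))$ST,
               as.data.frame(rowData(st@experiment))$ST)
  man <- jsonlite::read_json(file.path(d, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$T, 36)
  expect_equal(man$S, 2)
})
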