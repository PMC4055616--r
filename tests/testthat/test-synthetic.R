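# The calibrated station generator and the inverse profile builder.

test_that("the default region table carries the published summaries", {
  tbl <- defaultRegionTable()
  expect_equal(nrow(tbl), 8L)
  expect_equal(sum(tbl$n), 72)
  coastal <- tbl[tbl$region == "coastal", ]
  expect_equal(coastal$n, 26)
  expect_equal(c(coastal$pp_mean, coastal$pp_sd), c(248, 271))
  expect_equal(c(coastal$phyto_c_mean, coastal$phyto_c_sd), c(202, 187))
  expect_equal(c(coastal$chl_mean, coastal$chl_sd), c(3.5, 3.2))
  si <- tbl[tbl$region == "soiree_in", ]
  expect_equal(c(si$dsig_mean, si$dsig_sd), c(0.02, 0.01))
  expect_equal(c(si$uml_mean, si$uml_sd), c(72, 3))
  expect_equal(c(si$zeu_mean, si$zeu_sd), c(47, 1))
  expect_equal(unique(tbl$log_cp_correlation), 0.9)
})

test_that("region table round-trips through the long CSV format", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeRegionTable(defaultRegionTable(), path)
  back <- readRegionTable(path)
  orig <- defaultRegionTable()
  expect_equal(back[order(back$region), sort(names(back))],
               orig[order(orig$region), sort(names(orig))],
               ignore_attr = TRUE)
})

test_that("zero-sd parameters collapse every station onto the region means", {
  p <- defaultRegionTable()[1, ]
  for (f in c("temp", "no3", "dsig", "zeu", "uml", "chl", "phyto_c", "pp")) {
    p[[paste0(f, "_sd")]] <- 0
  }
  st <- sampleStationSummaries(p, n = 6, seed = 2)
  expect_equal(st$chl_mg_m3, rep(p$chl_mean, 6))
  expect_equal(st$phyto_c_mgc_m3, rep(p$phyto_c_mean, 6))
  expect_equal(st$pp_mgc_m3_d, rep(p$pp_mean, 6))
  expect_equal(st$temp_c, rep(p$temp_mean, 6))
  expect_equal(st$p_c, rep(p$pp_mean / p$phyto_c_mean, 6))
})

test_that("sampled marginals recover the configured moments (large n)", {
  p <- defaultRegionTable()[defaultRegionTable()$region == "coastal", ]
  st <- sampleStationSummaries(p, n = 20000, seed = 8)
  expect_equal(mean(st$pp_mgc_m3_d), 248, tolerance = 0.02)
  expect_equal(sd(st$pp_mgc_m3_d), 271, tolerance = 0.05)
  expect_equal(mean(st$chl_mg_m3), 3.5, tolerance = 0.02)
  expect_equal(sd(st$chl_mg_m3), 3.2, tolerance = 0.05)
  # turnover is derived, never drawn: mean P^C lands near pp/c with the
  # log-correlation tightening the ratio
  olig <- defaultRegionTable()[defaultRegionTable()$region == "oligotrophic_s", ]
  so <- sampleStationSummaries(olig, n = 20000, seed = 9)
  expect_true(mean(so$p_c) > 0.15 && mean(so$p_c) < 0.35)
  expect_equal(so$p_c, so$pp_mgc_m3_d / so$phyto_c_mgc_m3)
})

test_that("log-space carbon-production correlation follows the knob", {
  p <- defaultRegionTable()[defaultRegionTable()$region == "coastal", ]
  st <- sampleStationSummaries(p, n = 20000, seed = 5)
  expect_equal(cor(log(st$phyto_c_mgc_m3), log(st$pp_mgc_m3_d)), 0.9,
               tolerance = 0.02)
  expect_equal(cor(log(st$phyto_c_mgc_m3), log(st$chl_mg_m3)), 0.9,
               tolerance = 0.02)
  p$log_cp_correlation <- 0.3
  st2 <- sampleStationSummaries(p, n = 20000, seed = 5)
  expect_equal(cor(log(st2$phyto_c_mgc_m3), log(st2$pp_mgc_m3_d)), 0.3,
               tolerance = 0.05)
})

test_that("the profile builder realises its targets through the hydrography stage", {
  tg <- list(uml = 30, zeu = 60, dsig = 0.5, no3 = 5)
  prof <- buildStationProfile(tg, surface_temp = 15, station_id = "rt")
  hd <- suppressWarnings(deriveHydrography(prof))
  expect_equal(umlDepth(hd), 30, tolerance = 1)
  expect_equal(zeuDepth(hd), 60, tolerance = 0.5)
  expect_equal(deltaSigmaT(hd), 0.5, tolerance = 0.01)
  expect_equal(no3EuphoticBase(hd), 5, tolerance = 0.05)
  expect_false(attr(prof, "targets")$reconciled)
})

test_that("the weakly stratified polar regime builds and processes", {
  # mixed layer deeper than the euphotic zone, tiny density contrast
  tg <- list(uml = 72, zeu = 47, dsig = 0.02, no3 = 23.2)
  prof <- buildStationProfile(tg, surface_temp = 2.8, station_id = "polar")
  hd <- deriveHydrography(prof)
  expect_equal(zeuDepth(hd), 47, tolerance = 0.5)
  expect_equal(deltaSigmaT(hd), 0.02, tolerance = 0.01)
  expect_gt(umlDepth(hd), zeuDepth(hd))
  expect_equal(umlDepth(hd), 72, tolerance = 1)
})

test_that("profile sigma-t matches the intended column to inversion tolerance", {
  tg <- list(uml = 25, zeu = 70, dsig = 1.1, no3 = 8)
  prof <- buildStationProfile(tg, surface_temp = 22, station_id = "inv")
  sig <- sigmaT(prof@salinity, prof@temperature)
  sig0 <- sig[1]
  expect_equal(interpAtOracle(depths(prof), sig, 70) - sig0, 1.1,
               tolerance = 1e-4)
  expect_equal(interpAtOracle(depths(prof), sig, 25) - sig0, 0.125,
               tolerance = 1e-4)
})

test_that("unrealisable strong-stratification targets are reconciled", {
  # dsig >= 0.125 with uml >= zeu cannot exist in a monotone column:
  # density at the euphotic base already exceeds the criterion
  tg <- list(uml = 80, zeu = 60, dsig = 0.6, no3 = 6)
  prof <- buildStationProfile(tg, surface_temp = 14, station_id = "rec")
  t2 <- attr(prof, "targets")
  expect_true(t2$reconciled)
  expect_equal(t2$uml, 0.95 * 60)
  hd <- suppressWarnings(deriveHydrography(prof))
  expect_equal(umlDepth(hd), t2$uml, tolerance = 1)
  expect_equal(zeuDepth(hd), 60, tolerance = 0.5)
})

test_that("generateDataset is deterministic per seed and complete", {
  ds1 <- generateDataset(syntheticConfig(seed = 101))
  ds2 <- generateDataset(syntheticConfig(seed = 101))
  ds3 <- generateDataset(syntheticConfig(seed = 102))
  expect_equal(nrow(ds1$stations), 72)
  expect_length(ds1$profiles, 72)
  expect_equal(sort(unique(ds1$stations$region)),
               sort(defaultRegionTable()$region))
  expect_identical(ds1$stations, ds2$stations)
  expect_identical(as.data.frame(ds1$profiles[[30]]),
                   as.data.frame(ds2$profiles[[30]]))
  expect_false(identical(ds1$stations$pp_mgc_m3_d, ds3$stations$pp_mgc_m3_d))
  expect_identical(names(ds1$stations), names(ds3$stations))
})

test_that("generated files are byte-identical across runs with one seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generateDataset(syntheticConfig(seed = 55), out_dir = d1)
  generateDataset(syntheticConfig(seed = 55), out_dir = d2)
  for (f in c("stations.csv", "profiles.csv", "region_params.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  prof <- readProfiles(file.path(d1, "profiles.csv"))
  expect_length(prof, 72)
  st <- readStations(file.path(d1, "stations.csv"))
  expect_equal(nrow(st), 72)
})
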