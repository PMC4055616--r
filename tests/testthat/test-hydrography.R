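# Mixed-layer depth, euphotic depth, stratification and nitrate lookup.

test_that("DepthProfile validates and sorts its inputs", {
  dp <- DepthProfile("s1", depth = c(50, 0, 10), temperature = c(12, 15, 15),
                     salinity = 35)
  expect_equal(depths(dp), c(0, 10, 50))
  expect_equal(stationId(dp), "s1")
  expect_error(DepthProfile("s1", depth = c(0, 0, 10), temperature = 10,
                            salinity = 35), "duplicate")
  expect_error(DepthProfile("s1", depth = 5, temperature = 10, salinity = 35),
               "at least 2")
  expect_error(DepthProfile("s1", depth = c(10, 50), temperature = 10,
                            salinity = 35), "surface")
  expect_error(DepthProfile("s1", depth = c(0, 10), temperature = 10,
                            salinity = 35, par = c(-1, 5)), "PAR")
})

test_that("mixed layer depth interpolates the 0.125 crossing", {
  # sigma-t linear 26.000 -> 27.000 over 0 -> 100 m: crossing at 12.5 m
  z <- seq(0, 100, by = 10)
  p <- profileWithSigma(z, 26 + z / 100)
  res <- mixedLayerDepth(p)
  expect_equal(res$depth, 12.5, tolerance = 1e-6)
  expect_length(res$flag, 0L)

  # stepped profile: 26.0 at {0, 30}, 26.5 at {35, 100}
  p2 <- profileWithSigma(c(0, 30, 35, 100), c(26, 26, 26.5, 26.5))
  expect_equal(mixedLayerDepth(p2)$depth, 31.25, tolerance = 1e-6)
  # discrete-level variant returns the sampled level itself
  expect_equal(mixedLayerDepth(p2, interpolate = FALSE)$depth, 35)
})

test_that("an unstratified column flags uml_not_reached at the deepest level", {
  z <- seq(0, 100, by = 20)
  p <- profileWithSigma(z, rep(26, length(z)))
  res <- mixedLayerDepth(p)
  expect_equal(res$depth, 100)
  expect_equal(res$flag, "uml_not_reached")
})

test_that("mixed layer depth is monotone non-decreasing in the threshold", {
  z <- seq(0, 200, by = 10)
  p <- profileWithSigma(z, 25.5 + 1.5 * (z / 200)^2)
  d <- vapply(c(0.05, 0.125, 0.25, 0.5), function(th) {
    mixedLayerDepth(p, threshold = th)$depth
  }, numeric(1))
  expect_true(all(diff(d) >= 0))
})

test_that("euphotic depth is exact on exponential PAR profiles", {
  # PAR = 100 exp(-0.1 z): 1% level at ln(100)/0.1 = 46.0517 m
  z <- seq(0, 100, by = 5)
  p <- DepthProfile("s", z, 10, 35, par = 100 * exp(-0.1 * z))
  expect_equal(euphoticDepth(p)$depth, log(100) / 0.1, tolerance = 1e-6)
  # two-point sampling reproduces the same exponential exactly
  p2 <- DepthProfile("s", c(0, 50), 10, 35, par = c(100, 0.5))
  expect_equal(euphoticDepth(p2)$depth, log(100) / (log(100 / 0.5) / 50),
               tolerance = 1e-6)
  # sampling-grid independence for a fixed attenuation coefficient
  for (dz in c(2, 7, 19)) {
    zz <- seq(0, 120, by = dz)
    pk <- DepthProfile("s", zz, 10, 35, par = 55 * exp(-0.07 * zz))
    expect_equal(euphoticDepth(pk)$depth, log(100) / 0.07, tolerance = 1e-6)
  }
})

test_that("clear water beyond the profile flags par_floor_not_reached", {
  z <- seq(0, 100, by = 10)
  p <- DepthProfile("s", z, 10, 35, par = 100 * exp(-0.02 * z))
  res <- euphoticDepth(p)
  expect_equal(res$depth, 100)
  expect_equal(res$flag, "par_floor_not_reached")
})

test_that("euphotic depth rejects missing or non-positive surface PAR", {
  p <- DepthProfile("s", c(0, 50), 10, 35, par = c(NA, 10))
  expect_error(euphoticDepth(p), "shallowest")
})

test_that("stratification index interpolates sigma-t at the euphotic base", {
  z <- seq(0, 100, by = 10)
  p <- profileWithSigma(z, 26 + z / 100)
  expect_equal(stratificationIndex(p, 50), 0.5, tolerance = 1e-6)
  ph <- profileWithSigma(z, rep(26, length(z)))
  expect_equal(stratificationIndex(ph, 80), 0, tolerance = 1e-9)
  p3 <- profileWithSigma(c(0, 40, 120), c(25.8, 25.9, 27.1))
  expect_equal(stratificationIndex(p3, 80), 0.7, tolerance = 1e-6)
  expect_error(stratificationIndex(p, 150), class = "phytoCoverageError")
})

test_that("nitrate lookup interpolates, censors and checks coverage", {
  base <- function(no3, z = c(0, 100)) {
    DepthProfile("s", z, 10, 35, nitrate = no3)
  }
  expect_equal(nitrateAtEuphoticBase(base(c(0.1, 10)), 50)$value, 5.05)
  expect_length(nitrateAtEuphoticBase(base(c(0.1, 10)), 50)$flag, 0L)
  # below-detection surface replaced by the 0.05 limit, result flagged
  res <- nitrateAtEuphoticBase(base(c(0.01, 10)), 50)
  expect_equal(res$value, 5.025)
  expect_equal(res$flag, "no3_censored")
  # nitrate coverage must bracket the euphotic depth
  expect_error(nitrateAtEuphoticBase(base(c(1, 5), z = c(0, 40)), 80),
               class = "phytoCoverageError")
  # QC warning when the euphotic-base value is suspiciously low
  expect_warning(nitrateAtEuphoticBase(base(c(0.1, 0.2)), 50),
                 class = "phytoQC_lowNitrate")
})

test_that("deriveHydrography composes consistently and is order-invariant", {
  z <- seq(0, 150, by = 5)
  sig <- 26 + 1.2 * (1 - exp(-z / 40))
  par <- 1400 * exp(-0.05 * z)
  no3 <- 8 / (1 + exp(-(z - 60) / 10))
  p <- DepthProfile("s", z, tempForSigma(sig), 35, par = par, nitrate = no3)
  hd <- suppressWarnings(deriveHydrography(p))
  expect_s4_class(hd, "HydroDerived")
  expect_equal(deltaSigmaT(hd),
               stratificationIndex(p, zeuDepth(hd)), tolerance = 1e-9)
  expect_equal(sigmaTSurface(hd), sigmaT(35, p@temperature[1]))
  expect_true(umlDepth(hd) >= min(z) && umlDepth(hd) <= max(z))
  # same rows fed in scrambled order give the identical result
  ord <- sample(seq_along(z))
  p2 <- DepthProfile("s", z[ord], tempForSigma(sig)[ord], 35,
                     par = par[ord], nitrate = no3[ord])
  hd2 <- suppressWarnings(deriveHydrography(p2))
  expect_equal(as.data.frame(hd2), as.data.frame(hd))
})

test_that("homogeneous transparent water raises both not-reached flags", {
  z <- seq(0, 80, by = 10)
  p <- DepthProfile("s", z, tempForSigma(rep(26, length(z))), 35,
                    par = 500 * exp(-0.001 * z))
  hd <- deriveHydrography(p)
  expect_setequal(hydroFlags(hd), c("uml_not_reached", "par_floor_not_reached"))
  expect_true(is.na(no3EuphoticBase(hd)))
})

test_that("derived quantities converge under sampling-grid refinement", {
  sigOf <- function(z) 26 + 0.9 * (tanh((z - 45) / 18) + tanh(45 / 18)) / 2
  parOf <- function(z) 1300 * exp(-0.04 * z)
  no3Of <- function(z) 12 / (1 + exp(-(z - 70) / 15))
  derive <- function(dz) {
    z <- seq(0, 160, by = dz)
    p <- DepthProfile("s", z, tempForSigma(sigOf(z)), 35,
                      par = parOf(z), nitrate = no3Of(z))
    hd <- suppressWarnings(deriveHydrography(p))
    c(umlDepth(hd), zeuDepth(hd), deltaSigmaT(hd), no3EuphoticBase(hd))
  }
  coarse <- derive(16)
  mid <- derive(4)
  fine <- derive(1)
  expect_true(all(abs(fine - mid) <= abs(coarse - mid) + 1e-9))
  expect_lt(max(abs(fine - mid) / pmax(abs(fine), 0.1)), 0.02)
})
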