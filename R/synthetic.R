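# Synthetic station generator calibrated to the published regional summary
# tables: moment-matched lognormal marginals for positive skewed quantities,
# truncated-normal temperature, and depth profiles built by inversion so
# that the hydrography stage recovers known ground truth.

#' Default regional parameter table
#'
#' Station counts and the per-region mean/sd of sea surface temperature,
#' nitrate at the euphotic base, stratification, euphotic and mixed-layer
#' depths, chlorophyll a, phytoplankton carbon and primary production for
#' the eight study regions (two temperate and two oligotrophic open-ocean
#' sectors, an equatorial upwelling sector, a productive coastal embayment,
#' and the inside/outside stations of a Southern Ocean iron-release
#' experiment). Station counts sum to 72. `log_cp_correlation` is the
#' log-space correlation imposed between carbon biomass and primary
#' production within a region (and between chlorophyll and carbon); the
#' station-level scatter structure is not published, so it is a single
#' configurable knob, 0.9 by default.
#'
#' @return data.frame, one row per region.
#' @export
defaultRegionTable <- function() {
  tbl <- read.csv(text = "
region,n,temp_mean,temp_sd,no3_mean,no3_sd,dsig_mean,dsig_sd,zeu_mean,zeu_sd,uml_mean,uml_sd,chl_mean,chl_sd,phyto_c_mean,phyto_c_sd,pp_mean,pp_sd
temperate_n,8,15.9,3.5,6.7,1.6,0.6,0.5,68,23,64,35,0.44,0.56,30,22,13,15
temperate_s,4,13.4,4.5,9.8,4.2,0.4,0.2,57,22,50,15,0.71,0.29,34,10,15,6
oligotrophic_n,5,22.3,2.3,1.9,1.5,0.8,0.5,115,14,47,13,0.10,0.03,11,3,2.5,0.8
oligotrophic_s,13,24.4,2.9,0.9,1.2,0.9,0.6,126,24,59,22,0.13,0.07,9,2,2.1,0.8
upwelling,8,27.3,1.4,14.0,2.1,3.2,0.6,83,13,29,12,0.20,0.07,16,11,10,11
coastal,26,15.3,2.0,6.8,3.2,0.8,0.6,20,4,7,4,3.5,3.2,202,187,248,271
soiree_in,6,2.8,0.1,23.2,1.1,0.02,0.01,47,1,72,3,1.19,0.16,89,33,25,3
soiree_out,2,2.7,0.0,25.4,0.4,0.23,0.02,74,8,69,2,0.20,0.03,12,3,2.0,0.6
", stringsAsFactors = FALSE)
  tbl$log_cp_correlation <- 0.9
  tbl
}

#' @noRd
validateRegionParams <- function(params) {
  need <- c("region", "n", "temp_mean", "temp_sd", "no3_mean", "no3_sd",
            "dsig_mean", "dsig_sd", "zeu_mean", "zeu_sd", "uml_mean",
            "uml_sd", "chl_mean", "chl_sd", "phyto_c_mean", "phyto_c_sd",
            "pp_mean", "pp_sd", "log_cp_correlation")
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    phytoStop(sprintf("region parameters missing column(s): %s",
                      paste(missing, collapse = ", ")),
              class = "phytoConfigError")
  }
  means <- grep("_mean$", need, value = TRUE)
  sds <- grep("_sd$", need, value = TRUE)
  if (any(params$n < 1) ||
      any(as.matrix(params[means]) <= 0) ||
      any(as.matrix(params[sds]) < 0)) {
    phytoStop("region parameters need n >= 1, positive means, non-negative sds",
              class = "phytoConfigError")
  }
  if (any(abs(params$log_cp_correlation) >= 1)) {
    phytoStop("log_cp_correlation must be in (-1, 1)", class = "phytoConfigError")
  }
  invisible(params)
}

#' Synthetic dataset configuration
#'
#' @param seed integer seed; a fixed seed makes the whole dataset
#'   reproducible byte-for-byte.
#' @param surface_par surface PAR assigned to generated profiles
#'   (umol photons m\eqn{^{-2}} s\eqn{^{-1}}).
#' @param profile_grid vertical sampling interval of generated profiles (m,
#'   at most 5).
#' @param salinity_baseline fixed salinity of generated profiles (PSU,
#'   >= 26 so that density is monotone in temperature).
#' @param min_delta_sigma_t stratification floor used downstream when
#'   computing the resource supply index.
#' @return a named list of class `phytoSyntheticConfig`.
#' @export
syntheticConfig <- function(seed = 1L, surface_par = 1500,
                            profile_grid = 5, salinity_baseline = 35,
                            min_delta_sigma_t = 0.05) {
  if (profile_grid <= 0 || profile_grid > 5) {
    phytoStop("'profile_grid' must be in (0, 5] m", class = "phytoConfigError")
  }
  if (salinity_baseline < 26 || salinity_baseline > 42) {
    phytoStop("'salinity_baseline' must be in [26, 42] PSU",
              class = "phytoConfigError")
  }
  if (surface_par <= 0) phytoStop("'surface_par' must be > 0",
                                  class = "phytoConfigError")
  structure(list(seed = as.integer(seed), surface_par = surface_par,
                 profile_grid = profile_grid,
                 salinity_baseline = salinity_baseline,
                 min_delta_sigma_t = min_delta_sigma_t),
            class = "phytoSyntheticConfig")
}

# Lognormal parameters matching a target mean and sd:
# sdlog^2 = log(1 + (s/m)^2), meanlog = log(m) - sdlog^2 / 2.
#' @noRd
lnormParams <- function(m, s) {
  if (m <= 0 || s < 0) {
    phytoStop("lognormal moments need mean > 0 and sd >= 0",
              class = "phytoConfigError")
  }
  s2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

# Truncated-normal draws on the physical sea surface temperature range.
#' @noRd
rnormTrunc <- function(n, mean, sd, lo = -2, hi = 40) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

# Correlated standard-normal triple (chl, C, PP) with an AR(1)-style
# correlation structure: cor(chl, C) = cor(C, PP) = rho, cor(chl, PP) =
# rho^2 (chlorophyll and production conditionally independent given
# biomass). Positive definite for any |rho| < 1.
#' @noRd
rTripleNormal <- function(n, rho) {
  R <- rbind(c(1, rho, rho^2),
             c(rho, 1, rho),
             c(rho^2, rho, 1))
  z <- matrix(rnorm(3L * n), n, 3L) %*% chol(R)
  colnames(z) <- c("chl", "phyto_c", "pp")
  z
}

#' Draw station summaries for one region
#'
#' Surface biology is drawn from a trivariate lognormal whose chlorophyll,
#' carbon-biomass and primary-production marginals are moment-matched to the
#' region's printed mean and sd, with log-space correlation
#' `log_cp_correlation` between biomass and production (and between
#' chlorophyll and biomass). The biomass turnover rate is never drawn: it is
#' computed as pp / phyto_c so that any statement about \eqn{P^C} is an
#' honest consequence of the generator. Temperature is normal, truncated to
#' the physical range; the four hydrographic targets (nitrate at the
#' euphotic base, stratification, euphotic and mixed-layer depth) are
#' independent moment-matched lognormals. With all sds zero every station
#' equals the region means exactly.
#'
#' @param params one row of a region table (see [defaultRegionTable]).
#' @param n number of stations (default: the region's tabulated n).
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return data.frame of station records including the hydrographic target
#'   columns `no3_target, dsig_target, zeu_target, uml_target`.
#' @export
sampleStationSummaries <- function(params, n = NULL, seed = NULL) {
  params <- as.data.frame(params)
  if (nrow(params) != 1L) phytoStop("'params' must be a single region row")
  validateRegionParams(params)
  if (is.null(n)) n <- params$n
  n <- as.integer(n)
  withSeed(seed, {
    rho <- params$log_cp_correlation
    z <- rTripleNormal(n, rho)
    drawLnorm <- function(zcol, m, s) {
      p <- lnormParams(m, s)
      exp(p[["meanlog"]] + p[["sdlog"]] * zcol)
    }
    chl <- drawLnorm(z[, "chl"], params$chl_mean, params$chl_sd)
    phyto_c <- drawLnorm(z[, "phyto_c"], params$phyto_c_mean, params$phyto_c_sd)
    pp <- drawLnorm(z[, "pp"], params$pp_mean, params$pp_sd)
    temp <- rnormTrunc(n, params$temp_mean, params$temp_sd)
    hydro <- function(m, s) drawLnorm(rnorm(n), m, s)
    no3 <- hydro(params$no3_mean, params$no3_sd)
    # stratification capped at 5 kg m-3: beyond any observed
    # surface-to-euphotic-base density difference, and beyond what a
    # realisable (S <= 42, T >= -2) water column can express above a warm
    # or polar surface. Extreme tail draws are redrawn.
    dsig <- hydro(params$dsig_mean, params$dsig_sd)
    while (any(dsig > 5)) {
      dsig[dsig > 5] <- drawLnorm(rnorm(sum(dsig > 5)),
                                  params$dsig_mean, params$dsig_sd)
    }
    zeu <- hydro(params$zeu_mean, params$zeu_sd)
    uml <- hydro(params$uml_mean, params$uml_sd)
    data.frame(
      station_id = sprintf("%s_%02d", params$region, seq_len(n)),
      region = params$region,
      temp_c = temp,
      chl_mg_m3 = chl,
      phyto_c_mgc_m3 = phyto_c,
      pp_mgc_m3_d = pp,
      p_c = pp / phyto_c,
      c_to_chl = phyto_c / chl,
      no3_target = no3,
      dsig_target = dsig,
      zeu_target = zeu,
      uml_target = uml,
      stringsAsFactors = FALSE)
  })
}

#' Build a depth profile realising hydrographic targets
#'
#' Inverse construction: a piecewise-linear sigma-t profile is laid out so
#' that the hydrography stage recovers the targets - constant surface
#' density above a mixing knee, sigma-t reaching surface + 0.125 exactly at
#' the mixed-layer target and surface + `dsig` at the euphotic target; PAR
#' decays exponentially with attenuation ln(100)/zeu so the 1% level sits
#' at `zeu`; nitrate follows a logistic nitracline centred on `zeu` that
#' passes through `no3` there. Temperature at each level is obtained by
#' numerically inverting the package's own density code at the fixed
#' baseline salinity, so the profile is consistent with [sigmaT] to within
#' 1e-6 kg m\eqn{^{-3}}; where the target density would need water colder
#' than the freezing point, temperature is held at -2 deg C and salinity is
#' increased instead (haline stratification, as in polar water columns).
#' Target depths are inserted into the sampling grid, making the later
#' interpolation exact.
#'
#' Target quadruples with `dsig` >= 0.125 and a mixed layer at or below the
#' euphotic depth are unrealisable by any monotone density profile (the
#' 0.125 criterion would trip at or above the euphotic base); such draws are
#' reconciled by capping the mixed-layer target at 0.95 * zeu. In the
#' weak-stratification regime (`dsig` < 0.125) the criterion can only trip
#' below the euphotic base, so a mixed-layer target above it is raised to
#' 1.05 * zeu. The realised targets are attached to the profile as attribute
#' `targets` (with a `reconciled` flag).
#'
#' @param targets list or one-row data.frame with `uml`, `zeu`, `dsig`,
#'   `no3` (all > 0). Station-record columns `uml_target` etc. are also
#'   accepted.
#' @param surface_temp sea surface temperature of the station, deg C.
#' @param station_id identifier for the generated profile.
#' @param config a [syntheticConfig].
#' @return a [DepthProfile-class] with attribute `targets`.
#' @export
buildStationProfile <- function(targets, surface_temp,
                                station_id = "synthetic",
                                config = syntheticConfig()) {
  g <- function(nm, alt) {
    v <- targets[[nm]]
    if (is.null(v)) v <- targets[[alt]]
    if (is.null(v) || !is.finite(v) || v <= 0) {
      phytoStop(sprintf("target '%s' must be a positive number", nm),
                class = "phytoConstructionError")
    }
    as.numeric(v)
  }
  uml <- g("uml", "uml_target")
  zeu <- g("zeu", "zeu_target")
  dsig <- g("dsig", "dsig_target")
  no3 <- g("no3", "no3_target")
  stopifnotScalarNumeric(surface_temp, "surface_temp")
  crit <- 0.125
  reconciled <- FALSE
  if (dsig >= crit && uml >= zeu) {
    uml <- 0.95 * zeu
    reconciled <- TRUE
  } else if (dsig < crit && uml <= zeu) {
    uml <- 1.05 * zeu
    reconciled <- TRUE
  }
  S <- config$salinity_baseline
  sig0 <- sigmaT(S, surface_temp)
  # sigma-t knots: flat surface layer, then a monotone rise through the
  # mixed-layer criterion and the euphotic-base density, then a gentler
  # deep increase.
  knee <- 0.5 * min(uml, zeu)
  if (dsig >= crit) {
    kd <- c(0, knee, uml, zeu)
    kv <- sig0 + c(0, 0, crit, dsig)
  } else {
    kd <- c(0, knee, zeu, uml)
    kv <- sig0 + c(0, 0, dsig, crit)
  }
  bottom <- max(uml, zeu) * 1.3 + 20
  kd <- c(kd, bottom)
  kv <- c(kv, kv[length(kv)] + 0.5)
  depth <- sort(unique(c(seq(0, bottom, by = config$profile_grid),
                         kd[kd <= bottom])))
  sig <- approx(kd, kv, xout = depth, ties = "ordered")$y
  ts <- solveTSForSigmaT(sig, S)
  k_par <- log(100) / zeu
  par <- config$surface_par * exp(-k_par * depth)
  nitr <- 2 * no3 / (1 + exp(-(depth - zeu) / (zeu / 8)))
  prof <- DepthProfile(station_id, depth = depth, temperature = ts$temperature,
                       salinity = ts$salinity, par = par, nitrate = nitr)
  attr(prof, "targets") <- list(uml = uml, zeu = zeu, dsig = dsig, no3 = no3,
                                reconciled = reconciled)
  prof
}

#' Generate a full synthetic station dataset
#'
#' Draws every region of `regions` at its tabulated station count (summing
#' to 72 with the default table) and builds a physically consistent depth
#' profile per station. Deterministic for a fixed `config$seed`. When
#' `out_dir` is given, writes `stations.csv`, `profiles.csv` and
#' `region_params.csv` in the package's interchange formats.
#'
#' @param config a [syntheticConfig].
#' @param regions region parameter table (default [defaultRegionTable]).
#' @param out_dir optional output directory.
#' @return list with `stations` (data.frame), `profiles` (named list of
#'   [DepthProfile-class]), `regions` and `config`.
#' @export
generateDataset <- function(config = syntheticConfig(),
                            regions = defaultRegionTable(),
                            out_dir = NULL) {
  validateRegionParams(regions)
  stations <- withSeed(config$seed, {
    do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
      sampleStationSummaries(regions[i, ], seed = NULL)
    }))
  })
  rownames(stations) <- NULL
  profiles <- lapply(seq_len(nrow(stations)), function(i) {
    st <- stations[i, ]
    buildStationProfile(
      list(uml = st$uml_target, zeu = st$zeu_target,
           dsig = st$dsig_target, no3 = st$no3_target),
      surface_temp = st$temp_c, station_id = st$station_id, config = config)
  })
  names(profiles) <- stations$station_id
  ds <- list(stations = stations, profiles = profiles,
             regions = regions, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeStations(stations, file.path(out_dir, "stations.csv"))
    writeProfiles(profiles, file.path(out_dir, "profiles.csv"))
    writeRegionTable(regions, file.path(out_dir, "region_params.csv"))
    logMsg(sprintf("wrote synthetic dataset (%d stations) to %s",
                   nrow(stations), out_dir))
  }
  ds
}
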