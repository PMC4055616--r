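# Orchestration: attach derived physics and RSI to station records and run
# the full analysis (scaling fits, temperature and RSI correlations,
# chlorophyll bins, RSI-stratified temperature fits, regional summaries).

.soireeRegions <- c("soiree_in", "soiree_out")

#' Process one station: surface biology + derived physics + RSI
#'
#' Derives the hydrographic quantities from the station's profile, computes
#' the resource supply index and the biological rate metrics, and returns
#' the combined record. Stations of the iron-limited Southern Ocean
#' experiment regions are always marked RSI-excluded, regardless of their
#' stratification, because nitrate and light do not limit growth there. A
#' profile without usable nitrate yields an `NA` RSI and a logged warning
#' rather than an error.
#'
#' @param profile a [DepthProfile-class].
#' @param station one-row data.frame with at least `station_id, region,
#'   temp_c, chl_mg_m3, phyto_c_mgc_m3, pp_mgc_m3_d`.
#' @param min_delta_sigma_t stratification floor for RSI exclusion
#'   (default 0.05 kg m\eqn{^{-3}}).
#' @param soiree_regions region labels excluded from RSI on iron-limitation
#'   grounds.
#' @return one-row data.frame: the station record plus derived hydrography,
#'   `p_c`, `c_to_chl`, `rsi`, `term_nutrient`, `term_light`,
#'   `rsi_excluded`, `rsi_exclude_reason`, `flags`.
#' @export
processStation <- function(profile, station, min_delta_sigma_t = 0.05,
                           soiree_regions = .soireeRegions) {
  stopifnot(is(profile, "DepthProfile"))
  station <- as.data.frame(station)
  if (nrow(station) != 1L) phytoStop("'station' must be a single record")
  if (!identical(profile@station_id, station$station_id)) {
    phytoStop(sprintf("station_id mismatch: profile '%s' vs record '%s'",
                      profile@station_id, station$station_id),
              class = "phytoReconciliationError")
  }
  hd <- withCallingHandlers(
    deriveHydrography(profile),
    phytoQC = function(w) invokeRestart("muffleWarning"))
  rec <- data.frame(
    station_id = station$station_id,
    region = station$region,
    temp_c = station$temp_c,
    chl_mg_m3 = station$chl_mg_m3,
    phyto_c_mgc_m3 = station$phyto_c_mgc_m3,
    pp_mgc_m3_d = station$pp_mgc_m3_d,
    p_c = carbonTurnover(station$pp_mgc_m3_d, station$phyto_c_mgc_m3),
    c_to_chl = carbonToChl(station$phyto_c_mgc_m3, station$chl_mg_m3),
    sigma_t_surface = sigmaTSurface(hd),
    uml_depth_m = umlDepth(hd),
    euphotic_depth_m = zeuDepth(hd),
    delta_sigma_t = deltaSigmaT(hd),
    no3_zeu_umol_l = no3EuphoticBase(hd),
    flags = paste(hydroFlags(hd), collapse = ";"),
    stringsAsFactors = FALSE)
  no3 <- no3EuphoticBase(hd)
  if (!is.finite(no3) || deltaSigmaT(hd) <= 0) {
    reason <- if (!is.finite(no3)) "nitrate unavailable" else
                "non-positive stratification"
    logMsg(sprintf("station '%s': RSI undefined (%s)",
                   station$station_id, reason), level = "warn")
    rec$rsi <- NA_real_
    rec$term_nutrient <- NA_real_
    rec$term_light <- NA_real_
    rec$rsi_excluded <- TRUE
    rec$rsi_exclude_reason <- reason
  } else {
    ri <- resourceSupplyIndex(no3, deltaSigmaT(hd), zeuDepth(hd),
                              umlDepth(hd),
                              min_delta_sigma_t = min_delta_sigma_t,
                              station_id = station$station_id)
    rec$rsi <- ri$rsi
    rec$term_nutrient <- ri$term_nutrient
    rec$term_light <- ri$term_light
    rec$rsi_excluded <- ri$excluded
    rec$rsi_exclude_reason <- ri$exclude_reason
  }
  if (station$region %in% soiree_regions) {
    rec$rsi_excluded <- TRUE
    rec$rsi_exclude_reason <- "iron-limited (Soiree)"
  }
  rec
}

#' Process a full station set
#'
#' Pairs each station record with its profile by `station_id` and applies
#' [processStation]. Orphans on either side are a reconciliation error
#' listing the offending ids.
#'
#' @param stations data.frame of station records.
#' @param profiles named list of [DepthProfile-class] objects.
#' @inheritParams processStation
#' @return data.frame of processed station records.
#' @export
processStations <- function(stations, profiles, min_delta_sigma_t = 0.05,
                            soiree_regions = .soireeRegions) {
  ids_s <- stations$station_id
  ids_p <- vapply(profiles, stationId, character(1))
  names(profiles) <- ids_p
  orphans <- c(setdiff(ids_s, ids_p), setdiff(ids_p, ids_s))
  if (length(orphans)) {
    phytoStop(sprintf("unpaired station ids: %s",
                      paste(orphans, collapse = ", ")),
              class = "phytoReconciliationError")
  }
  out <- do.call(rbind, lapply(seq_len(nrow(stations)), function(i) {
    processStation(profiles[[stations$station_id[i]]], stations[i, ],
                   min_delta_sigma_t = min_delta_sigma_t,
                   soiree_regions = soiree_regions)
  }))
  rownames(out) <- NULL
  out
}

#' @noRd
regionSummaries <- function(records) {
  cols <- c(temp_c = "temp_c", chl = "chl_mg_m3", phyto_c = "phyto_c_mgc_m3",
            pp = "pp_mgc_m3_d", p_c = "p_c", c_to_chl = "c_to_chl",
            no3_zeu = "no3_zeu_umol_l", delta_sigma_t = "delta_sigma_t",
            zeu = "euphotic_depth_m", uml = "uml_depth_m")
  do.call(rbind, lapply(unique(records$region), function(rg) {
    d <- records[records$region == rg, ]
    row <- data.frame(region = rg, n = nrow(d), stringsAsFactors = FALSE)
    for (nm in names(cols)) {
      v <- d[[cols[[nm]]]]
      row[[paste0(nm, "_mean")]] <- mean(v, na.rm = TRUE)
      row[[paste0(nm, "_sd")]] <- if (sum(is.finite(v)) > 1) sd(v, na.rm = TRUE)
                                  else NA_real_
    }
    ok <- !d$rsi_excluded & is.finite(d$rsi)
    row$rsi_mean <- if (any(ok)) mean(d$rsi[ok]) else NA_real_
    row$rsi_sd <- if (sum(ok) > 1) sd(d$rsi[ok]) else NA_real_
    row$n_rsi <- sum(ok)
    row
  }))
}

#' Run the full analysis over processed station records
#'
#' Computes, in order: the three cross-station scaling fits on log10 scale
#' (production vs carbon biomass, production vs chlorophyll, carbon vs
#' chlorophyll) as reduced major-axis regressions with bootstrap-over-cases
#' confidence intervals; the Pearson correlation of the biomass turnover
#' rate \eqn{P^C} with sea surface temperature over all stations; the
#' Pearson correlation of \eqn{P^C} with the resource supply index over
#' RSI-included stations; chlorophyll-bin summaries of \eqn{P^C} with
#' pairwise Mann-Whitney tests; ordinary least-squares fits of \eqn{P^C} on
#' temperature within the low-RSI (< 10 mmolN kg\eqn{^{-1}}) and
#' intermediate-RSI (10-20) strata; and per-region summary tables. Analyses
#' whose preconditions fail (too few stations) are recorded as skipped with
#' a reason and the run continues. Log10 transforms are applied here, never
#' stored, so station tables stay in natural units.
#'
#' @param records data.frame from [processStations] (or any table with the
#'   same columns).
#' @param n_boot bootstrap repetitions for the scaling fits (default 2000).
#' @param ci_level confidence level (default 0.95).
#' @param seed seed for the bootstrap streams.
#' @param rsi_strata_breaks two numbers: upper edge of the low stratum and
#'   of the intermediate stratum (default 10 and 20 mmolN kg\eqn{^{-1}}).
#' @param bin_edges chlorophyll bin edges for [binByChl].
#' @return an [AnalysisReport-class] object.
#' @export
runAnalysis <- function(records, n_boot = 2000L, ci_level = 0.95, seed = 1L,
                        rsi_strata_breaks = c(10, 20),
                        bin_edges = .defaultChlEdges) {
  stopifnot(is.data.frame(records))
  skipped <- list()
  fits <- list()
  specs <- list(
    pp_vs_c = c("phyto_c_mgc_m3", "pp_mgc_m3_d"),
    pp_vs_chl = c("chl_mg_m3", "pp_mgc_m3_d"),
    c_vs_chl = c("chl_mg_m3", "phyto_c_mgc_m3"))
  for (k in seq_along(specs)) {
    nm <- names(specs)[k]
    xv <- records[[specs[[k]][1L]]]
    yv <- records[[specs[[k]][2L]]]
    ok <- is.finite(xv) & is.finite(yv) & xv > 0 & yv > 0
    if (sum(ok) < 3L) {
      skipped[[nm]] <- sprintf("only %d stations with positive %s and %s",
                               sum(ok), specs[[k]][1L], specs[[k]][2L])
      next
    }
    fits[[nm]] <- bootstrapRmaCi(log10(xv[ok]), log10(yv[ok]),
                                 n_boot = n_boot, ci_level = ci_level,
                                 seed = as.integer(seed) + k)
  }
  ok_t <- is.finite(records$p_c) & is.finite(records$temp_c)
  temp_correlation <- if (sum(ok_t) >= 3L) {
    pearsonTest(records$temp_c[ok_t], records$p_c[ok_t])
  } else {
    skipped$temp_correlation <- "fewer than 3 stations with P^C and temperature"
    list()
  }
  ok_r <- !records$rsi_excluded & is.finite(records$rsi) & is.finite(records$p_c)
  rsi_correlation <- if (sum(ok_r) >= 3L) {
    pearsonTest(records$rsi[ok_r], records$p_c[ok_r])
  } else {
    skipped$rsi_correlation <- "fewer than 3 RSI-included stations"
    list()
  }
  ok_c <- is.finite(records$chl_mg_m3) & records$chl_mg_m3 > 0 &
          is.finite(records$p_c)
  bins <- binByChl(records$chl_mg_m3[ok_c], records$p_c[ok_c],
                   edges = bin_edges)
  lab <- levels(bins$assignment)
  tests <- list()
  for (i in seq_along(lab)) {
    for (j in seq_along(lab)) {
      if (j <= i) next
      a <- records$p_c[ok_c][bins$assignment == lab[i]]
      b <- records$p_c[ok_c][bins$assignment == lab[j]]
      if (length(a) >= 2L && length(b) >= 2L) {
        tests[[length(tests) + 1L]] <- mannWhitney(a, b, lab[i], lab[j])
      }
    }
  }
  chl_bin_tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(group_a = character(0), group_b = character(0),
               u_statistic = numeric(0), p_value = numeric(0),
               n_a = integer(0), n_b = integer(0))
  strata <- list(
    low_rsi = ok_r & records$rsi < rsi_strata_breaks[1L],
    mid_rsi = ok_r & records$rsi >= rsi_strata_breaks[1L] &
              records$rsi <= rsi_strata_breaks[2L])
  rsi_strata <- list()
  for (nm in names(strata)) {
    sel <- strata[[nm]] & is.finite(records$temp_c)
    if (sum(sel) >= 3L && sd(records$temp_c[sel]) > 0) {
      f <- olsFit(records$temp_c[sel], records$p_c[sel])
      f$temp_range <- range(records$temp_c[sel])
      rsi_strata[[nm]] <- f
    } else {
      skipped[[paste0("rsi_strata_", nm)]] <-
        sprintf("only %d usable stations in stratum", sum(sel))
    }
  }
  exclusions <- records[records$rsi_excluded,
                        c("station_id", "region", "rsi_exclude_reason")]
  rownames(exclusions) <- NULL
  new("AnalysisReport",
      fits = fits,
      temp_correlation = temp_correlation,
      rsi_correlation = rsi_correlation,
      chl_bins = bins$summary,
      chl_bin_tests = chl_bin_tests,
      rsi_strata = rsi_strata,
      region_summaries = regionSummaries(records),
      exclusions = exclusions,
      skipped = skipped,
      provenance = list(
        seed = as.integer(seed),
        n_boot = as.integer(n_boot),
        ci_level = ci_level,
        rsi_strata_breaks = rsi_strata_breaks,
        bin_edges = bin_edges[is.finite(bin_edges)],
        package_version = as.character(packageVersion("phytoRSI"))))
}

#' @noRd
fitAsList <- function(fit, name) {
  list(name = name, n = fit@n, slope = fit@slope, intercept = fit@intercept,
       pearson_r = fit@pearson_r, ci_level = fit@ci_level,
       slope_ci = fit@slope_ci, intercept_ci = fit@intercept_ci,
       n_boot = fit@n_boot, seed = fit@seed,
       n_degenerate = fit@n_degenerate, method = fit@method)
}

#' Serialise an analysis report to plain lists
#'
#' @param report an [AnalysisReport-class].
#' @return a nested list suitable for [jsonlite::write_json].
#' @export
reportAsList <- function(report) {
  stopifnot(is(report, "AnalysisReport"))
  list(
    fits = lapply(setNames(names(report@fits), names(report@fits)),
                  function(nm) fitAsList(report@fits[[nm]], nm)),
    temp_correlation = report@temp_correlation,
    rsi_correlation = report@rsi_correlation,
    chl_bins = report@chl_bins,
    chl_bin_tests = report@chl_bin_tests,
    rsi_strata = report@rsi_strata,
    region_summaries = report@region_summaries,
    exclusions = report@exclusions,
    skipped = report@skipped,
    provenance = report@provenance)
}

#' Write an analysis report to disk
#'
#' Writes `report.json` plus CSV side tables `region_summaries.csv` and
#' `chl_bins.csv` into `dir`.
#'
#' @param report an [AnalysisReport-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(reportAsList(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  write.csv(report@region_summaries, file.path(dir, "region_summaries.csv"),
            row.names = FALSE)
  write.csv(report@chl_bins, file.path(dir, "chl_bins.csv"), row.names = FALSE)
  invisible(dir)
}
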