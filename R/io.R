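# CSV interchange formats. Long-format profile tables, per-station surface
# tables, derived-hydrography tables and the long-format region table.

#' Read depth profiles from a long-format CSV
#'
#' Expected header: `station_id,depth_m,temp_c,sal_psu,par,no3_umol_l`;
#' empty cells are allowed for `par` and `no3_umol_l`. Rows may appear in
#' any depth order.
#'
#' @param path CSV file path.
#' @return named list of [DepthProfile-class] objects.
#' @export
readProfiles <- function(path) {
  if (!file.exists(path)) {
    phytoStop(sprintf("profile file not found: %s", path))
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "depth_m", "temp_c", "sal_psu", "par", "no3_umol_l")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    phytoStop(sprintf("%s: missing column(s) %s", path,
                      paste(missing, collapse = ", ")))
  }
  out <- lapply(split(df, df$station_id), function(d) {
    DepthProfile(d$station_id[1L], depth = d$depth_m,
                 temperature = d$temp_c, salinity = d$sal_psu,
                 par = d$par, nitrate = d$no3_umol_l)
  })
  out[unique(df$station_id)]
}

#' Write depth profiles to a long-format CSV
#'
#' @param profiles list of [DepthProfile-class] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeProfiles <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, as.data.frame))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a per-station surface table
#'
#' Expected header: `station_id,region,temp_c,chl_mg_m3,phyto_c_mgc_m3,
#' pp_mgc_m3_d`. Values are validated (positive chlorophyll and biomass,
#' non-negative production); a violation is reported with the station and
#' field name.
#'
#' @param path CSV file path.
#' @return data.frame of station records.
#' @export
readStations <- function(path) {
  if (!file.exists(path)) {
    phytoStop(sprintf("station file not found: %s", path))
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "region", "temp_c", "chl_mg_m3",
            "phyto_c_mgc_m3", "pp_mgc_m3_d")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    phytoStop(sprintf("%s: missing column(s) %s", path,
                      paste(missing, collapse = ", ")))
  }
  checkPositive <- function(col, strict = TRUE) {
    v <- df[[col]]
    bad <- if (strict) which(!is.finite(v) | v <= 0) else
                       which(!is.finite(v) | v < 0)
    if (length(bad)) {
      phytoStop(sprintf("station '%s': invalid %s (%s)",
                        df$station_id[bad[1L]], col, v[bad[1L]]))
    }
  }
  checkPositive("chl_mg_m3")
  checkPositive("phyto_c_mgc_m3")
  checkPositive("pp_mgc_m3_d", strict = FALSE)
  if (anyDuplicated(df$station_id)) {
    phytoStop(sprintf("%s: duplicated station_id", path))
  }
  df
}

#' Write a per-station surface table
#'
#' @param stations data.frame of station records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeStations <- function(stations, path) {
  write.csv(stations, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write derived hydrography to CSV
#'
#' Columns: `station_id,sigma_t_surface,uml_depth_m,euphotic_depth_m,
#' delta_sigma_t,no3_zeu_umol_l,flags` (flags semicolon-joined).
#'
#' @param derived list of [HydroDerived-class] objects or the data.frame
#'   produced by [processStations].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeHydroDerived <- function(derived, path) {
  df <- if (is.data.frame(derived)) derived
        else do.call(rbind, lapply(derived, as.data.frame))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a region parameter table in long format
#'
#' Rows of `region,n,field,mean,sd`; `log_cp_correlation` is stored as a
#' field with an empty sd.
#'
#' @param regions wide region table (see [defaultRegionTable]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeRegionTable <- function(regions, path) {
  fields <- c("temp", "no3", "dsig", "zeu", "uml", "chl", "phyto_c", "pp")
  rows <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    rbind(
      do.call(rbind, lapply(fields, function(f) {
        data.frame(region = r$region, n = r$n, field = f,
                   mean = r[[paste0(f, "_mean")]],
                   sd = r[[paste0(f, "_sd")]], stringsAsFactors = FALSE)
      })),
      data.frame(region = r$region, n = r$n, field = "log_cp_correlation",
                 mean = r$log_cp_correlation, sd = NA_real_,
                 stringsAsFactors = FALSE))
  }))
  write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a long-format region parameter table
#'
#' @param path CSV of `region,n,field,mean,sd` rows.
#' @return wide region table as from [defaultRegionTable].
#' @export
readRegionTable <- function(path) {
  if (!file.exists(path)) {
    phytoStop(sprintf("region table not found: %s", path))
  }
  long <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "n", "field", "mean", "sd")
  if (!all(need %in% names(long))) {
    phytoStop(sprintf("%s: expected columns %s", path,
                      paste(need, collapse = ", ")))
  }
  regions <- unique(long$region)
  wide <- do.call(rbind, lapply(regions, function(rg) {
    d <- long[long$region == rg, ]
    row <- data.frame(region = rg, n = d$n[1L], stringsAsFactors = FALSE)
    for (i in seq_len(nrow(d))) {
      f <- d$field[i]
      if (f == "log_cp_correlation") {
        row$log_cp_correlation <- d$mean[i]
      } else {
        row[[paste0(f, "_mean")]] <- d$mean[i]
        row[[paste0(f, "_sd")]] <- d$sd[i]
      }
    }
    row
  }))
  if (is.null(wide$log_cp_correlation)) wide$log_cp_correlation <- 0.9
  validateRegionParams(wide)
  wide
}
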