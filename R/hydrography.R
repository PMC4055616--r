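# Derived physics from depth profiles: sigma-t profile, mixed-layer depth,
# euphotic depth, stratification index, nitrate at the euphotic base.

#' @noRd
profileSigmaT <- function(profile) {
  sigmaT(profile@salinity, profile@temperature)
}

#' Upper mixed layer depth by the density-difference criterion
#'
#' The UML depth is the first depth at which sigma-t exceeds the surface
#' value (shallowest sampled level, not extrapolated to 0 m) by `threshold`
#' kg m\eqn{^{-3}}. The crossing is located by linear interpolation between
#' the bracketing sampled levels; with `interpolate = FALSE` the first
#' sampled level at or beyond the threshold is returned instead (the
#' discrete-level variant, for comparison). If the threshold is never
#' exceeded the deepest sampled depth is returned with flag
#' `uml_not_reached`.
#'
#' @param profile a [DepthProfile-class].
#' @param threshold density offset, kg m\eqn{^{-3}} (default 0.125).
#' @param interpolate interpolate between bracketing levels (default) or
#'   return the sampled level itself.
#' @return list with `depth` (m) and `flag` (character, possibly empty).
#' @export
mixedLayerDepth <- function(profile, threshold = 0.125, interpolate = TRUE) {
  stopifnot(is(profile, "DepthProfile"))
  validObject(profile)
  stopifnotScalarNumeric(threshold, "threshold")
  if (threshold <= 0) phytoStop("'threshold' must be > 0")
  sig <- profileSigmaT(profile)
  z <- profile@depth
  target <- sig[1L] + threshold
  idx <- which(sig >= target)[1L]
  if (is.na(idx)) {
    return(list(depth = z[length(z)], flag = "uml_not_reached"))
  }
  if (!interpolate || idx == 1L) {
    return(list(depth = z[idx], flag = character(0)))
  }
  z1 <- z[idx - 1L]; z2 <- z[idx]
  s1 <- sig[idx - 1L]; s2 <- sig[idx]
  list(depth = z1 + (z2 - z1) * (target - s1) / (s2 - s1), flag = character(0))
}

#' Euphotic zone depth from a PAR profile
#'
#' Depth at which PAR falls to `fraction` of its value at the shallowest
#' sampled level (1% by default), located by linear interpolation in
#' log(PAR) against depth - exact for exponentially attenuated light. If the
#' profile never reaches the fraction, the deepest PAR-sampled depth is
#' returned with flag `par_floor_not_reached`.
#'
#' @param profile a [DepthProfile-class] with PAR at the shallowest level.
#' @param fraction surviving light fraction defining the euphotic base
#'   (default 0.01).
#' @return list with `depth` (m) and `flag` (character, possibly empty).
#' @export
euphoticDepth <- function(profile, fraction = 0.01) {
  stopifnot(is(profile, "DepthProfile"))
  validObject(profile)
  stopifnotScalarNumeric(fraction, "fraction")
  if (fraction <= 0 || fraction >= 1) phytoStop("'fraction' must be in (0, 1)")
  keep <- is.finite(profile@par)
  if (!keep[1L]) {
    phytoStop(sprintf("profile '%s': PAR missing at the shallowest level",
                      profile@station_id))
  }
  z <- profile@depth[keep]
  p <- profile@par[keep]
  if (any(p <= 0)) {
    phytoStop(sprintf("profile '%s': non-positive PAR value", profile@station_id))
  }
  target <- fraction * p[1L]
  idx <- which(p <= target)[1L]
  if (is.na(idx)) {
    return(list(depth = z[length(z)], flag = "par_floor_not_reached"))
  }
  if (idx == 1L) {
    return(list(depth = z[1L], flag = character(0)))
  }
  z1 <- z[idx - 1L]; z2 <- z[idx]
  l1 <- log(p[idx - 1L]); l2 <- log(p[idx])
  list(depth = z1 + (z2 - z1) * (l1 - log(target)) / (l1 - l2),
       flag = character(0))
}

#' Stratification index: sigma-t difference over the euphotic layer
#'
#' Sigma-t linearly interpolated at `euphotic_depth` minus sigma-t at the
#' shallowest sampled level. May be near zero in well-mixed columns or
#' negative for inverted profiles; returned as computed.
#'
#' @param profile a [DepthProfile-class].
#' @param euphotic_depth depth of the euphotic base (m), inside the sampled
#'   range.
#' @return delta sigma-t in kg m\eqn{^{-3}}.
#' @export
stratificationIndex <- function(profile, euphotic_depth) {
  stopifnot(is(profile, "DepthProfile"))
  validObject(profile)
  stopifnotScalarNumeric(euphotic_depth, "euphotic_depth")
  sig <- profileSigmaT(profile)
  s_zeu <- interpAt(profile@depth, sig, euphotic_depth, "sigma-t")
  s_zeu - sig[1L]
}

#' Nitrate at the base of the euphotic zone
#'
#' Linear interpolation of the nitrate profile at `euphotic_depth`. Input
#' levels below the analytical detection limit are replaced by the limit (a
#' conservative upper bound) before interpolating; when any level was
#' censored the result carries flag `no3_censored`. A QC warning (condition
#' class `phytoQC_lowNitrate`) is emitted when the interpolated value is at
#' or below 0.2 umol L\eqn{^{-1}}, unusually low for the euphotic base.
#'
#' @param profile a [DepthProfile-class] with nitrate at two or more levels
#'   bracketing `euphotic_depth`.
#' @param euphotic_depth depth of the euphotic base (m).
#' @param detection_limit analytical detection limit, umol L\eqn{^{-1}}
#'   (default 0.05).
#' @return list with `value` (umol L\eqn{^{-1}}) and `flag`.
#' @export
nitrateAtEuphoticBase <- function(profile, euphotic_depth,
                                  detection_limit = 0.05) {
  stopifnot(is(profile, "DepthProfile"))
  validObject(profile)
  stopifnotScalarNumeric(euphotic_depth, "euphotic_depth")
  stopifnotScalarNumeric(detection_limit, "detection_limit")
  keep <- is.finite(profile@nitrate)
  if (sum(keep) < 2L) {
    phytoStop(sprintf("profile '%s': nitrate present at fewer than 2 levels",
                      profile@station_id), class = "phytoCoverageError")
  }
  z <- profile@depth[keep]
  no3 <- profile@nitrate[keep]
  if (euphotic_depth < min(z) || euphotic_depth > max(z)) {
    phytoStop(sprintf(
      "profile '%s': nitrate coverage [%.1f, %.1f] m does not bracket %.1f m",
      profile@station_id, min(z), max(z), euphotic_depth),
      class = "phytoCoverageError")
  }
  censored <- no3 < detection_limit
  no3[censored] <- detection_limit
  value <- approx(z, no3, xout = euphotic_depth, ties = "ordered")$y
  if (value <= 0.2) {
    qcWarn(sprintf(
      "profile '%s': nitrate at the euphotic base is %.3f umol L-1 (<= 0.2)",
      profile@station_id, value), class = "phytoQC_lowNitrate")
  }
  list(value = value,
       flag = if (any(censored)) "no3_censored" else character(0))
}

#' Derive all hydrographic quantities for one station
#'
#' Composes [mixedLayerDepth], [euphoticDepth], [stratificationIndex] and
#' [nitrateAtEuphoticBase] into a [HydroDerived-class] object. When the
#' profile carries nitrate at fewer than two levels the nitrate field is
#' `NA` (no flag); a nitrate profile that does not bracket the euphotic
#' depth raises a coverage error.
#'
#' @param profile a [DepthProfile-class].
#' @param threshold UML density criterion, kg m\eqn{^{-3}} (default 0.125).
#' @param fraction euphotic light fraction (default 0.01).
#' @param detection_limit nitrate detection limit, umol L\eqn{^{-1}}
#'   (default 0.05).
#' @param interpolate passed to [mixedLayerDepth].
#' @return a [HydroDerived-class] object.
#' @export
deriveHydrography <- function(profile, threshold = 0.125, fraction = 0.01,
                              detection_limit = 0.05, interpolate = TRUE) {
  stopifnot(is(profile, "DepthProfile"))
  validObject(profile)
  sig <- profileSigmaT(profile)
  uml <- mixedLayerDepth(profile, threshold = threshold,
                         interpolate = interpolate)
  zeu <- euphoticDepth(profile, fraction = fraction)
  dsig <- stratificationIndex(profile, zeu$depth)
  if (sum(is.finite(profile@nitrate)) >= 2L) {
    no3 <- nitrateAtEuphoticBase(profile, zeu$depth,
                                 detection_limit = detection_limit)
  } else {
    no3 <- list(value = NA_real_, flag = character(0))
  }
  new("HydroDerived",
      station_id = profile@station_id,
      sigma_t_surface = sig[1L],
      uml_depth = uml$depth,
      euphotic_depth = zeu$depth,
      delta_sigma_t = dsig,
      no3_euphotic_base = no3$value,
      flags = c(uml$flag, zeu$flag, no3$flag))
}

#' @rdname HydroDerived-class
#' @param row.names,optional,... ignored.
#' @export
as.data.frame.HydroDerived <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(station_id = x@station_id,
             sigma_t_surface = x@sigma_t_surface,
             uml_depth_m = x@uml_depth,
             euphotic_depth_m = x@euphotic_depth,
             delta_sigma_t = x@delta_sigma_t,
             no3_zeu_umol_l = x@no3_euphotic_base,
             flags = paste(x@flags, collapse = ";"))
}
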