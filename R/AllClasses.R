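# S4 containers for the profile-to-growth-analysis pipeline.

.hydroFlagSet <- c("uml_not_reached", "par_floor_not_reached", "no3_censored")

#' DepthProfile: one station's co-registered vertical arrays
#'
#' Holds a single station's CTD-style profile: depth (m, positive downward),
#' temperature (deg C), practical salinity (PSU), photosynthetically active
#' radiation (any consistent unit, optional per level) and nitrate
#' (umol L\eqn{^{-1}}, optional per level). Depths are stored strictly
#' increasing; the constructor sorts its inputs, so row order of a profile
#' table does not matter.
#'
#' @slot station_id single station identifier.
#' @slot depth numeric, strictly increasing, shallowest level at 5 m or less.
#' @slot temperature numeric, same length as depth.
#' @slot salinity numeric, same length as depth.
#' @slot par numeric, positive where present (`NA` allowed).
#' @slot nitrate numeric, non-negative where present (`NA` allowed).
#' @export
setClass("DepthProfile",
  representation(
    station_id = "character",
    depth = "numeric",
    temperature = "numeric",
    salinity = "numeric",
    par = "numeric",
    nitrate = "numeric"
  )
)

setValidity("DepthProfile", function(object) {
  msgs <- character(0)
  n <- length(object@depth)
  lens <- c(length(object@temperature), length(object@salinity),
            length(object@par), length(object@nitrate))
  if (length(object@station_id) != 1L || is.na(object@station_id)) {
    msgs <- c(msgs, "station_id must be a single non-missing string")
  }
  if (any(lens != n)) {
    msgs <- c(msgs, "all profile arrays must have the same length as depth")
  }
  if (n < 2L) msgs <- c(msgs, "a profile needs at least 2 depth levels")
  if (anyNA(object@depth) || anyNA(object@temperature) || anyNA(object@salinity)) {
    msgs <- c(msgs, "depth, temperature and salinity must be complete")
  } else {
    if (any(diff(object@depth) <= 0)) {
      msgs <- c(msgs, "depth must be strictly increasing (no duplicate depths)")
    }
    if (object@depth[1L] > 5) {
      msgs <- c(msgs, "shallowest level must be at 5 m or less (a surface sample)")
    }
  }
  par_ok <- object@par[is.finite(object@par)]
  if (length(par_ok) && any(par_ok <= 0)) {
    msgs <- c(msgs, "PAR values must be > 0 where present")
  }
  no3_ok <- object@nitrate[is.finite(object@nitrate)]
  if (length(no3_ok) && any(no3_ok < 0)) {
    msgs <- c(msgs, "nitrate values must be >= 0 where present")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a DepthProfile
#'
#' @param station_id station identifier.
#' @param depth depths in m, positive downward (any order; sorted internally).
#' @param temperature temperatures in deg C.
#' @param salinity practical salinities (PSU).
#' @param par PAR values (> 0 where present), or `NULL`.
#' @param nitrate nitrate in umol L\eqn{^{-1}} (>= 0 where present), or `NULL`.
#' @return a [DepthProfile-class] object.
#' @examples
#' dp <- DepthProfile("st1", depth = c(0, 10, 50, 100),
#'                    temperature = c(15, 15, 12, 10), salinity = 35.5,
#'                    par = c(1500, 800, 60, 2))
#' @export
DepthProfile <- function(station_id, depth, temperature, salinity,
                         par = NULL, nitrate = NULL) {
  n <- length(depth)
  recycle <- function(x) {
    if (is.null(x)) return(rep(NA_real_, n))
    if (length(x) == 1L) return(rep(as.numeric(x), n))
    as.numeric(x)
  }
  depth <- as.numeric(depth)
  if (anyDuplicated(depth)) {
    phytoStop(sprintf("profile '%s' has duplicate depths", station_id))
  }
  ord <- order(depth)
  new("DepthProfile",
      station_id = as.character(station_id),
      depth = depth[ord],
      temperature = recycle(temperature)[ord],
      salinity = recycle(salinity)[ord],
      par = recycle(par)[ord],
      nitrate = recycle(nitrate)[ord])
}

#' HydroDerived: per-station derived physics
#'
#' Result of [deriveHydrography]: surface sigma-t, upper mixed layer depth
#' (density criterion), euphotic depth (1% PAR), stratification index
#' (sigma-t difference surface to euphotic base), nitrate at the euphotic
#' base, and quality flags.
#'
#' @slot station_id station identifier.
#' @slot sigma_t_surface kg m\eqn{^{-3}} at the shallowest sampled level.
#' @slot uml_depth m.
#' @slot euphotic_depth m.
#' @slot delta_sigma_t kg m\eqn{^{-3}} (may be <= 0 for inverted profiles).
#' @slot no3_euphotic_base umol L\eqn{^{-1}} (`NA` when nitrate is absent).
#' @slot flags subset of `uml_not_reached`, `par_floor_not_reached`,
#'   `no3_censored`.
#' @export
setClass("HydroDerived",
  representation(
    station_id = "character",
    sigma_t_surface = "numeric",
    uml_depth = "numeric",
    euphotic_depth = "numeric",
    delta_sigma_t = "numeric",
    no3_euphotic_base = "numeric",
    flags = "character"
  )
)

setValidity("HydroDerived", function(object) {
  msgs <- character(0)
  if (!all(object@flags %in% .hydroFlagSet)) {
    msgs <- c(msgs, sprintf("flags must be a subset of {%s}",
                            paste(.hydroFlagSet, collapse = ", ")))
  }
  for (s in c("sigma_t_surface", "uml_depth", "euphotic_depth", "delta_sigma_t")) {
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s))) {
      msgs <- c(msgs, sprintf("%s must be a single finite number", s))
    }
  }
  if (length(object@no3_euphotic_base) != 1L) {
    msgs <- c(msgs, "no3_euphotic_base must be a single number (NA allowed)")
  } else if (is.finite(object@no3_euphotic_base) &&
             object@no3_euphotic_base < 0) {
    msgs <- c(msgs, "no3_euphotic_base must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' RMAFit: a reduced major-axis regression fit
#'
#' Slope and intercept of the model-II (reduced major-axis) line, the
#' Pearson correlation of the fitted variables, and - after
#' [bootstrapRmaCi] - bootstrap-over-cases confidence intervals.
#'
#' @slot slope RMA slope, sign(r) * sd(y)/sd(x).
#' @slot intercept mean(y) - slope * mean(x).
#' @slot pearson_r Pearson correlation.
#' @slot n number of cases.
#' @slot ci_level confidence level of the intervals (`NA` before bootstrap).
#' @slot slope_ci length-2 numeric (lo, hi).
#' @slot intercept_ci length-2 numeric (lo, hi).
#' @slot n_boot bootstrap repetitions.
#' @slot seed seed used for resampling.
#' @slot n_degenerate zero-variance resamples that had to be redrawn.
#' @slot method `"percentile"` or `"bca"`.
#' @export
setClass("RMAFit",
  representation(
    slope = "numeric",
    intercept = "numeric",
    pearson_r = "numeric",
    n = "integer",
    ci_level = "numeric",
    slope_ci = "numeric",
    intercept_ci = "numeric",
    n_boot = "integer",
    seed = "integer",
    n_degenerate = "integer",
    method = "character"
  ),
  prototype(
    ci_level = NA_real_,
    slope_ci = c(NA_real_, NA_real_),
    intercept_ci = c(NA_real_, NA_real_),
    n_boot = 0L,
    seed = NA_integer_,
    n_degenerate = 0L,
    method = NA_character_
  )
)

setValidity("RMAFit", function(object) {
  msgs <- character(0)
  if (length(object@slope_ci) != 2L || length(object@intercept_ci) != 2L) {
    msgs <- c(msgs, "confidence intervals must have length 2")
  }
  if (is.finite(object@pearson_r) && is.finite(object@slope) &&
      object@pearson_r != 0 &&
      sign(object@slope) != sign(object@pearson_r)) {
    msgs <- c(msgs, "slope and pearson_r must agree in sign")
  }
  if (length(msgs)) msgs else TRUE
})

#' AnalysisReport: the full numeric analysis of a station dataset
#'
#' Produced by [runAnalysis]. Contains the three log10 scaling fits
#' (production vs carbon, production vs chlorophyll, carbon vs chlorophyll),
#' the temperature and RSI correlations of the biomass turnover rate, the
#' chlorophyll-bin summaries with pairwise rank tests, the temperature fits
#' within RSI strata, per-region summary tables, the exclusion list and the
#' run provenance.
#'
#' @slot fits named list of [RMAFit-class] objects.
#' @slot temp_correlation list(r, p, n).
#' @slot rsi_correlation list(r, p, n).
#' @slot chl_bins data.frame of per-bin n, mean and sd of \eqn{P^C}.
#' @slot chl_bin_tests data.frame of pairwise Mann-Whitney results.
#' @slot rsi_strata list of per-stratum OLS fits of \eqn{P^C} on temperature.
#' @slot region_summaries data.frame shaped like the regional summary tables.
#' @slot exclusions data.frame of stations excluded from RSI analyses.
#' @slot skipped named list of analyses skipped, with reasons.
#' @slot provenance list(seed, n_boot, ci_level, ...).
#' @export
setClass("AnalysisReport",
  representation(
    fits = "list",
    temp_correlation = "list",
    rsi_correlation = "list",
    chl_bins = "data.frame",
    chl_bin_tests = "data.frame",
    rsi_strata = "list",
    region_summaries = "data.frame",
    exclusions = "data.frame",
    skipped = "list",
    provenance = "list"
  )
)
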