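# Generics and accessor/show methods.

#' @rdname DepthProfile-class
#' @param x,object a `DepthProfile`, `HydroDerived` or `RMAFit` object.
#' @export
setGeneric("stationId", function(x) standardGeneric("stationId"))

#' @rdname DepthProfile-class
#' @export
setGeneric("depths", function(x) standardGeneric("depths"))

#' @rdname HydroDerived-class
#' @param x,object a `HydroDerived` object.
#' @export
setGeneric("umlDepth", function(x) standardGeneric("umlDepth"))

#' @rdname HydroDerived-class
#' @export
setGeneric("zeuDepth", function(x) standardGeneric("zeuDepth"))

#' @rdname HydroDerived-class
#' @export
setGeneric("deltaSigmaT", function(x) standardGeneric("deltaSigmaT"))

#' @rdname HydroDerived-class
#' @export
setGeneric("no3EuphoticBase", function(x) standardGeneric("no3EuphoticBase"))

#' @rdname HydroDerived-class
#' @export
setGeneric("sigmaTSurface", function(x) standardGeneric("sigmaTSurface"))

#' @rdname HydroDerived-class
#' @export
setGeneric("hydroFlags", function(x) standardGeneric("hydroFlags"))

#' @rdname RMAFit-class
#' @param x,object an `RMAFit` object.
#' @export
setGeneric("pearsonR", function(x) standardGeneric("pearsonR"))

#' @rdname RMAFit-class
#' @export
setGeneric("slopeCI", function(x) standardGeneric("slopeCI"))

#' @rdname RMAFit-class
#' @export
setGeneric("interceptCI", function(x) standardGeneric("interceptCI"))

#' @rdname DepthProfile-class
#' @export
setMethod("stationId", "DepthProfile", function(x) x@station_id)

#' @rdname HydroDerived-class
#' @export
setMethod("stationId", "HydroDerived", function(x) x@station_id)

#' @rdname DepthProfile-class
#' @export
setMethod("depths", "DepthProfile", function(x) x@depth)

#' @rdname DepthProfile-class
#' @export
setMethod("length", "DepthProfile", function(x) length(x@depth))

#' Profile contents as a data.frame
#'
#' @param x a [DepthProfile-class].
#' @param row.names,optional,... ignored; present for generic consistency.
#' @return data.frame with columns `station_id, depth_m, temp_c, sal_psu,
#'   par, no3_umol_l`.
#' @export
as.data.frame.DepthProfile <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(station_id = x@station_id, depth_m = x@depth,
             temp_c = x@temperature, sal_psu = x@salinity,
             par = x@par, no3_umol_l = x@nitrate)
}

#' @rdname HydroDerived-class
#' @export
setMethod("umlDepth", "HydroDerived", function(x) x@uml_depth)

#' @rdname HydroDerived-class
#' @export
setMethod("zeuDepth", "HydroDerived", function(x) x@euphotic_depth)

#' @rdname HydroDerived-class
#' @export
setMethod("deltaSigmaT", "HydroDerived", function(x) x@delta_sigma_t)

#' @rdname HydroDerived-class
#' @export
setMethod("no3EuphoticBase", "HydroDerived", function(x) x@no3_euphotic_base)

#' @rdname HydroDerived-class
#' @export
setMethod("sigmaTSurface", "HydroDerived", function(x) x@sigma_t_surface)

#' @rdname HydroDerived-class
#' @export
setMethod("hydroFlags", "HydroDerived", function(x) x@flags)

#' @rdname RMAFit-class
#' @export
setMethod("coef", "RMAFit", function(object, ...) {
  c(intercept = object@intercept, slope = object@slope)
})

#' @rdname RMAFit-class
#' @export
setMethod("nobs", "RMAFit", function(object, ...) object@n)

#' @rdname RMAFit-class
#' @export
setMethod("pearsonR", "RMAFit", function(x) x@pearson_r)

#' @rdname RMAFit-class
#' @export
setMethod("slopeCI", "RMAFit", function(x) x@slope_ci)

#' @rdname RMAFit-class
#' @export
setMethod("interceptCI", "RMAFit", function(x) x@intercept_ci)

setMethod("show", "DepthProfile", function(object) {
  cat(sprintf("DepthProfile '%s': %d levels, %.1f-%.1f m\n",
              object@station_id, length(object@depth),
              min(object@depth), max(object@depth)))
  cat(sprintf("  temperature %.2f-%.2f degC, salinity %.2f-%.2f\n",
              min(object@temperature), max(object@temperature),
              min(object@salinity), max(object@salinity)))
  if (any(is.finite(object@par))) {
    cat(sprintf("  PAR at %d levels, nitrate at %d levels\n",
                sum(is.finite(object@par)), sum(is.finite(object@nitrate))))
  }
  invisible(NULL)
})

setMethod("show", "HydroDerived", function(object) {
  cat(sprintf("HydroDerived '%s'\n", object@station_id))
  cat(sprintf("  sigma-t surface : %8.4f kg m-3\n", object@sigma_t_surface))
  cat(sprintf("  UML depth       : %8.2f m\n", object@uml_depth))
  cat(sprintf("  euphotic depth  : %8.2f m\n", object@euphotic_depth))
  cat(sprintf("  delta sigma-t   : %8.4f kg m-3\n", object@delta_sigma_t))
  cat(sprintf("  NO3 @ zeu       : %8.3f umol L-1\n", object@no3_euphotic_base))
  if (length(object@flags)) {
    cat("  flags           :", paste(object@flags, collapse = "; "), "\n")
  }
  invisible(NULL)
})

setMethod("show", "RMAFit", function(object) {
  cat(sprintf("RMAFit (n = %d): slope %.4f, intercept %.4f, r %.4f\n",
              object@n, object@slope, object@intercept, object@pearson_r))
  if (is.finite(object@ci_level)) {
    cat(sprintf("  %d%% %s CI: slope (%.4f, %.4f), intercept (%.4f, %.4f)\n",
                round(100 * object@ci_level), object@method,
                object@slope_ci[1], object@slope_ci[2],
                object@intercept_ci[1], object@intercept_ci[2]))
    cat(sprintf("  n_boot = %d, seed = %d, degenerate resamples redrawn = %d\n",
                object@n_boot, object@seed, object@n_degenerate))
  }
  invisible(NULL)
})

setMethod("show", "AnalysisReport", function(object) {
  cat("AnalysisReport\n")
  for (nm in names(object@fits)) {
    f <- object@fits[[nm]]
    cat(sprintf("  %-12s slope %.3f (%.3f, %.3f), r %.3f, n %d\n",
                nm, f@slope, f@slope_ci[1], f@slope_ci[2], f@pearson_r, f@n))
  }
  tc <- object@temp_correlation
  if (length(tc)) {
    cat(sprintf("  P^C vs temperature: r %.3f (p %.3g, n %d)\n",
                tc$r, tc$p, tc$n))
  }
  rc <- object@rsi_correlation
  if (length(rc)) {
    cat(sprintf("  P^C vs RSI        : r %.3f (p %.3g, n %d)\n",
                rc$r, rc$p, rc$n))
  }
  if (nrow(object@exclusions)) {
    cat(sprintf("  RSI exclusions    : %d stations\n", nrow(object@exclusions)))
  }
  if (length(object@skipped)) {
    cat("  skipped:", paste(names(object@skipped), collapse = ", "), "\n")
  }
  invisible(NULL)
})
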