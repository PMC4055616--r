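# The resource supply index and its regional summaries.

.knownRegions <- c("temperate_n", "temperate_s", "oligotrophic_n",
                   "oligotrophic_s", "upwelling", "coastal",
                   "soiree_in", "soiree_out")

#' Resource supply index
#'
#' \deqn{RSI = (NO3_{1\%PAR} / \Delta\sigma_t) \times (1\%PARz / UMLz)}
#'
#' The nutrient term (umol L\eqn{^{-1}} per kg m\eqn{^{-3}}, identically
#' mmol m\eqn{^{-3}} per kg m\eqn{^{-3}} = mmolN kg\eqn{^{-1}}) grows with
#' the nitrate pool below the euphotic zone and shrinks as stratification
#' isolates it from the surface; the dimensionless light term compares the
#' euphotic depth with the mixed-layer depth, separating shallow, well-lit
#' mixed layers from deeply mixed, light-limited ones. The index depicts
#' broad between-region contrasts, not local nutrient flux.
#'
#' Stations whose stratification is weaker than `min_delta_sigma_t` are
#' marked excluded (the index diverges as \eqn{\Delta\sigma_t \to 0}); their
#' RSI value is still reported for inspection.
#'
#' Vectorised over its four numeric arguments.
#'
#' @param no3_zeu nitrate at the euphotic base, umol L\eqn{^{-1}} (> 0).
#' @param delta_sigma_t surface-to-euphotic-base sigma-t difference,
#'   kg m\eqn{^{-3}} (> 0).
#' @param euphotic_depth 1% PAR depth, m (> 0).
#' @param uml_depth upper mixed layer depth, m (> 0).
#' @param min_delta_sigma_t stratification floor below which stations are
#'   flagged excluded (default 0.05 kg m\eqn{^{-3}}).
#' @param station_id optional station identifiers.
#' @return data.frame with columns `station_id, rsi, term_nutrient,
#'   term_light, excluded, exclude_reason`.
#' @examples
#' resourceSupplyIndex(6.8, 0.8, 20, 7)  # RSI = 8.5 * 2.857 = 24.29
#' @export
resourceSupplyIndex <- function(no3_zeu, delta_sigma_t, euphotic_depth,
                                uml_depth, min_delta_sigma_t = 0.05,
                                station_id = NULL) {
  n <- max(length(no3_zeu), length(delta_sigma_t),
           length(euphotic_depth), length(uml_depth))
  no3 <- rep_len(as.numeric(no3_zeu), n)
  dsig <- rep_len(as.numeric(delta_sigma_t), n)
  zeu <- rep_len(as.numeric(euphotic_depth), n)
  uml <- rep_len(as.numeric(uml_depth), n)
  if (any(!is.finite(zeu)) || any(zeu <= 0) ||
      any(!is.finite(uml)) || any(uml <= 0)) {
    phytoStop("euphotic_depth and uml_depth must be positive and finite",
              class = "phytoDomainError")
  }
  if (any(!is.finite(no3)) || any(no3 <= 0) ||
      any(!is.finite(dsig)) || any(dsig <= 0)) {
    phytoStop("no3_zeu and delta_sigma_t must be positive and finite",
              class = "phytoDomainError")
  }
  term_nutrient <- no3 / dsig
  term_light <- zeu / uml
  excluded <- dsig < min_delta_sigma_t
  data.frame(
    station_id = if (is.null(station_id)) sprintf("st%03d", seq_len(n))
                 else rep_len(as.character(station_id), n),
    rsi = term_nutrient * term_light,
    term_nutrient = term_nutrient,
    term_light = term_light,
    excluded = excluded,
    exclude_reason = ifelse(excluded,
      sprintf("weak stratification (delta_sigma_t < %.3g)", min_delta_sigma_t),
      ""),
    stringsAsFactors = FALSE)
}

#' Regional summary of RSI results
#'
#' Arithmetic mean and sample standard deviation of RSI over the
#' non-excluded stations of each region, with counts of stations and
#' exclusions. Regions whose stations are all excluded (the iron-limited
#' Southern Ocean experiment, for instance) are reported with `n = 0` and
#' `NA` mean and sd.
#'
#' @param results data.frame as returned by [resourceSupplyIndex] (columns
#'   `rsi` and `excluded`).
#' @param regions character vector of region labels, one per row of
#'   `results`.
#' @param known_regions vector of admissible labels; an unknown label is a
#'   validation error.
#' @return data.frame with columns `region, mean_rsi, sd_rsi, n, n_excluded`.
#' @export
summarizeRsiByRegion <- function(results, regions,
                                 known_regions = .knownRegions) {
  stopifnot(is.data.frame(results), all(c("rsi", "excluded") %in% names(results)))
  regions <- as.character(regions)
  if (length(regions) != nrow(results)) {
    phytoStop("'regions' must have one label per result row")
  }
  unknown <- setdiff(unique(regions), known_regions)
  if (length(unknown)) {
    phytoStop(sprintf("unknown region label(s): %s",
                      paste(unknown, collapse = ", ")))
  }
  out <- lapply(unique(regions), function(rg) {
    sel <- regions == rg
    ok <- sel & !results$excluded
    data.frame(region = rg,
               mean_rsi = if (any(ok)) mean(results$rsi[ok]) else NA_real_,
               sd_rsi = if (sum(ok) > 1L) sd(results$rsi[ok]) else NA_real_,
               n = sum(ok),
               n_excluded = sum(sel & results$excluded),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
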