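# Biological rate metrics and the biovolume-to-carbon conversion.

#' Default biovolume-to-carbon conversion table
#'
#' Literature-standard protist power laws, carbon per cell (pgC) =
#' a * volume(um^3)^b: one row for diatoms (large vacuoles dilute carbon)
#' and one for non-diatom protists. The coefficients the original field
#' campaigns used live in their cited protocols; this table is
#' configuration - a substitute default - not hard-coded truth, and can be
#' extended or replaced (e.g. with fixed picoplankton factors expressed as
#' additional rows).
#'
#' @return data.frame with columns `group, a, b`.
#' @export
defaultCarbonTable <- function() {
  data.frame(group = c("diatom", "non_diatom"),
             a = c(0.288, 0.216),
             b = c(0.811, 0.939),
             stringsAsFactors = FALSE)
}

#' Read a biovolume-to-carbon conversion table
#'
#' Small config CSV of `group,a,b` rows (see [defaultCarbonTable] for the
#' shipped defaults and the meaning of the coefficients).
#'
#' @param path CSV file path.
#' @return validated data.frame with columns `group, a, b`.
#' @export
readCarbonTable <- function(path) {
  if (!file.exists(path)) {
    phytoStop(sprintf("conversion table not found: %s", path),
              class = "phytoConfigError")
  }
  validateCarbonTable(read.csv(path, stringsAsFactors = FALSE))
}

#' @noRd
validateCarbonTable <- function(table) {
  if (!is.data.frame(table) || !all(c("group", "a", "b") %in% names(table))) {
    phytoStop("conversion table needs columns 'group', 'a', 'b'",
              class = "phytoConfigError")
  }
  if (any(table$a <= 0) || any(table$b <= 0) || any(table$b > 1.2)) {
    phytoStop("conversion coefficients must satisfy a > 0 and 0 < b <= 1.2",
              class = "phytoConfigError")
  }
  invisible(table)
}

#' Carbon content of a single cell from its biovolume
#'
#' @param volume cell biovolume, um\eqn{^3} (> 0).
#' @param group taxon group label, matched against `table$group`.
#' @param table conversion table (see [defaultCarbonTable]).
#' @return carbon per cell, pgC.
#' @examples
#' cellCarbon(1000, "diatom")  # 0.288 * 1000^0.811 = 78.0 pgC
#' @export
cellCarbon <- function(volume, group, table = defaultCarbonTable()) {
  validateCarbonTable(table)
  if (any(volume <= 0)) phytoStop("'volume' must be > 0", class = "phytoDomainError")
  i <- match(group, table$group)
  if (anyNA(i)) {
    phytoStop(sprintf("unknown taxon group '%s'; known groups: %s",
                      group[which(is.na(i))[1L]],
                      paste(table$group, collapse = ", ")),
              class = "phytoConfigError")
  }
  table$a[i] * volume^table$b[i]
}

#' Community carbon biomass from biovolume and abundance
#'
#' Per-cell carbon (pgC, power law from `table`) times abundance
#' (cells mL\eqn{^{-1}}) gives pgC mL\eqn{^{-1}}; converting pg to mg
#' (1e-9) and mL to m\eqn{^3} (1e6) leaves a net factor of 1e-3, so the
#' community biomass is returned in mgC m\eqn{^{-3}}.
#'
#' @param volume cell biovolume, um\eqn{^3} (> 0).
#' @param abundance cell abundance, cells mL\eqn{^{-1}} (> 0).
#' @param group taxon group label.
#' @param table conversion table (see [defaultCarbonTable]).
#' @return carbon biomass, mgC m\eqn{^{-3}}.
#' @examples
#' biovolumeToCarbon(1000, 1000, "diatom")  # 78.0 mgC m-3
#' @export
biovolumeToCarbon <- function(volume, abundance, group,
                              table = defaultCarbonTable()) {
  if (any(abundance <= 0)) {
    phytoStop("'abundance' must be > 0", class = "phytoDomainError")
  }
  cellCarbon(volume, group, table) * abundance * 1e-3
}

#' Biomass-specific carbon fixation rate (biomass turnover)
#'
#' \eqn{P^C = P / C}: the daily carbon fixation rate divided by
#' phytoplankton carbon biomass, in d\eqn{^{-1}} - equivalent to the
#' intrinsic community growth rate when losses are small over the
#' incubation.
#'
#' @param primary_production carbon fixation, mgC m\eqn{^{-3}} d\eqn{^{-1}}
#'   (>= 0).
#' @param phyto_c phytoplankton carbon biomass, mgC m\eqn{^{-3}} (> 0).
#' @return turnover rate, d\eqn{^{-1}}.
#' @examples
#' carbonTurnover(248, 202)  # 1.228 d-1
#' @export
carbonTurnover <- function(primary_production, phyto_c) {
  if (any(!is.finite(phyto_c)) || any(phyto_c <= 0)) {
    phytoStop("'phyto_c' must be positive and finite", class = "phytoDomainError")
  }
  if (any(primary_production < 0, na.rm = TRUE)) {
    phytoStop("'primary_production' must be >= 0", class = "phytoDomainError")
  }
  primary_production / phyto_c
}

#' Carbon to chlorophyll a ratio
#'
#' @param phyto_c phytoplankton carbon, mgC m\eqn{^{-3}}.
#' @param chl_a chlorophyll a, mg m\eqn{^{-3}} (> 0).
#' @return dimensionless C:Chl a ratio.
#' @export
carbonToChl <- function(phyto_c, chl_a) {
  if (any(!is.finite(chl_a)) || any(chl_a <= 0)) {
    phytoStop("'chl_a' must be positive and finite", class = "phytoDomainError")
  }
  phyto_c / chl_a
}
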