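# EOS-80 one-atmosphere seawater density (Millero & Poisson polynomial).

#' Sigma-t from salinity and temperature (EOS-80, one atmosphere)
#'
#' Density anomaly \eqn{\sigma_t = \rho(S, T, p = 0) - 1000} kg m\eqn{^{-3}}
#' from the UNESCO EOS-80 one-atmosphere polynomial (pure-water density plus
#' the salinity terms in S, S^1.5 and S^2). This is the conventional sigma-t
#' used for density-criterion mixed-layer depths; no pressure dependence.
#'
#' Inputs must lie in the standard's validity range: salinity 0-42,
#' temperature -2 to 40 deg C. Vectorised elementwise; scalar arguments are
#' recycled.
#'
#' @param salinity practical salinity (PSU).
#' @param temperature temperature (deg C, IPTS-68 assumed).
#' @return sigma-t in kg m\eqn{^{-3}}.
#' @examples
#' sigmaT(35, 5)   # 27.67547
#' sigmaT(0, 5)    # -0.03325
#' sigmaT(35, 25)  # 23.34306
#' @export
sigmaT <- function(salinity, temperature) {
  n <- max(length(salinity), length(temperature))
  S <- rep_len(as.numeric(salinity), n)
  T <- rep_len(as.numeric(temperature), n)
  if (anyNA(S) || anyNA(T)) phytoStop("salinity and temperature must be non-missing")
  bad <- which(S < 0 | S > 42)
  if (length(bad)) {
    phytoStop(sprintf("salinity %.4g outside EOS-80 validity range [0, 42]",
                      S[bad[1L]]), class = "phytoRangeError")
  }
  bad <- which(T < -2 | T > 40)
  if (length(bad)) {
    phytoStop(sprintf("temperature %.4g outside EOS-80 validity range [-2, 40]",
                      T[bad[1L]]), class = "phytoRangeError")
  }
  # density of Standard Mean Ocean Water
  rho_w <- 999.842594 + T * (6.793952e-2 + T * (-9.095290e-3 +
             T * (1.001685e-4 + T * (-1.120083e-6 + T * 6.536332e-9))))
  A <- 8.24493e-1 + T * (-4.0899e-3 + T * (7.6438e-5 +
         T * (-8.2467e-7 + T * 5.3875e-9)))
  B <- -5.72466e-3 + T * (1.0227e-4 + T * (-1.6546e-6))
  C <- 4.8314e-4
  rho_w + A * S + B * S^1.5 + C * S * S - 1000
}

# Invert sigma-t for temperature at fixed salinity. Valid for salinities
# >= 26 PSU, where one-atmosphere density is strictly decreasing in
# temperature over [-2, 40] (the freshwater density maximum near 4 degC has
# vanished). Vectorised over `sigma`: coarse inverse interpolation on a
# cached temperature grid, then two Newton polish steps.
#' @noRd
solveTemperatureForSigmaT <- function(sigma, salinity, tol = 1e-6) {
  if (salinity < 26) {
    phytoStop("temperature inversion requires salinity >= 26 (monotone density)",
              class = "phytoConstructionError")
  }
  t_grid <- seq(-2, 40, by = 0.02)
  s_grid <- sigmaT(salinity, t_grid)
  lo <- s_grid[length(s_grid)]  # sigma at 40 degC
  hi <- s_grid[1L]              # sigma at -2 degC
  if (any(sigma < lo - 1e-9 | sigma > hi + 1e-9)) {
    phytoStop(sprintf(
      "target sigma-t %.4f not achievable at salinity %.2f (range %.4f to %.4f)",
      sigma[which(sigma < lo - 1e-9 | sigma > hi + 1e-9)[1L]], salinity, lo, hi),
      class = "phytoConstructionError")
  }
  # sigma decreases with T, so interpolate on the reversed grid
  T0 <- approx(rev(s_grid), rev(t_grid), xout = pmin(pmax(sigma, lo), hi),
               ties = "ordered")$y
  h <- 1e-3
  for (i in 1:3) {
    f <- sigmaT(salinity, T0) - sigma
    fp <- (sigmaT(salinity, pmin(T0 + h, 40)) -
           sigmaT(salinity, pmax(T0 - h, -2))) /
          (pmin(T0 + h, 40) - pmax(T0 - h, -2))
    T0 <- pmin(pmax(T0 - f / fp, -2), 40)
  }
  err <- max(abs(sigmaT(salinity, T0) - sigma))
  if (err > tol) {
    phytoStop(sprintf("sigma-t inversion failed to converge (residual %.2e)", err),
              class = "phytoConstructionError")
  }
  T0
}

# Hybrid (T, S) inversion for a target sigma-t column: thermal
# stratification at the baseline salinity wherever the target density is
# reachable above the freezing point, haline stratification (T held at
# -2 degC, salinity solved) below that - the structure of polar water
# columns, where cold surface water overlies saltier deep water.
#' @noRd
solveTSForSigmaT <- function(sigma, salinity, tol = 1e-6) {
  n <- length(sigma)
  temp <- rep(NA_real_, n)
  sal <- rep(salinity, n)
  cap <- sigmaT(salinity, -2)
  thermal <- sigma <= cap
  if (any(thermal)) {
    temp[thermal] <- solveTemperatureForSigmaT(sigma[thermal], salinity, tol)
  }
  if (any(!thermal)) {
    smax <- sigmaT(42, -2) - 0.02
    if (any(sigma > smax)) {
      phytoStop(sprintf(
        "target sigma-t %.3f not achievable for any salinity <= 42",
        max(sigma)), class = "phytoConstructionError")
    }
    temp[!thermal] <- -2
    s <- rep(41, sum(!thermal))
    for (i in 1:30) {
      f <- sigmaT(s, -2) - sigma[!thermal]
      fp <- (sigmaT(pmin(s + 1e-3, 42), -2) - sigmaT(s - 1e-3, -2)) /
            (pmin(s + 1e-3, 42) - (s - 1e-3))
      s <- pmin(pmax(s - f / fp, salinity), 42)
      if (max(abs(f)) < tol / 2) break
    }
    if (max(abs(sigmaT(s, -2) - sigma[!thermal])) > tol) {
      phytoStop("salinity inversion failed to converge",
                class = "phytoConstructionError")
    }
    sal[!thermal] <- s
  }
  list(temperature = temp, salinity = sal)
}
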