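# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# One-atmosphere seawater density anomaly, typed directly from the
# standard's published coefficient table (no Horner nesting, explicit
# powers) as an independent transcription of the same polynomial.
sigmaOracle <- function(S, Tc) {
  rw <- 999.842594 +
    6.793952e-2 * Tc -
    9.095290e-3 * Tc^2 +
    1.001685e-4 * Tc^3 -
    1.120083e-6 * Tc^4 +
    6.536332e-9 * Tc^5
  A <- 0.824493 - 4.0899e-3 * Tc + 7.6438e-5 * Tc^2 -
    8.2467e-7 * Tc^3 + 5.3875e-9 * Tc^4
  B <- -5.72466e-3 + 1.0227e-4 * Tc - 1.6546e-6 * Tc^2
  rw + A * S + B * S^1.5 + 4.8314e-4 * S^2 - 1000
}

# Temperature producing a given sigma-t at fixed salinity (oracle-side
# inversion, used to construct test profiles with prescribed densities).
tempForSigma <- function(sigma, S = 35) {
  vapply(sigma, function(sg) {
    uniroot(function(Tc) sigmaOracle(S, Tc) - sg, c(-2, 40),
            tol = 1e-12)$root
  }, numeric(1))
}

# Build a DepthProfile whose sigma-t takes prescribed values at prescribed
# depths (temperature solved by the oracle at S = 35).
profileWithSigma <- function(depth, sigma, par = NULL, nitrate = NULL,
                             id = "test") {
  DepthProfile(id, depth = depth, temperature = tempForSigma(sigma),
               salinity = 35, par = par, nitrate = nitrate)
}

# Brute-force RMA slope: minimise the sum of triangle areas
# sum (y - a - b x)^2 / |b| over b, with a chosen so the line passes
# through the centroid.
rmaSlopeBrute <- function(x, y) {
  obj <- function(b) {
    a <- mean(y) - b * mean(x)
    sum((y - a - b * x)^2) / abs(b)
  }
  sgn <- sign(cor(x, y))
  optimize(function(b) obj(sgn * b), c(1e-4, 1e4))$minimum * sgn
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# C(n_a + n_b, n_a) group assignments of the pooled values.
mannWhitneyEnum <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  n <- length(pooled)
  uOf <- function(av, bv) {
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  u_obs <- uOf(a, b)
  combos <- combn(n, na)
  u_all <- apply(combos, 2, function(ix) uOf(pooled[ix], pooled[-ix]))
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(u = u_obs, p = min(1, p))
}

# Plain linear interpolation used on the oracle side.
interpAtOracle <- function(x, y, x0) approx(x, y, xout = x0)$y

tempRegions <- c("temperate_n", "temperate_s")
oligRegions <- c("oligotrophic_n", "oligotrophic_s")
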