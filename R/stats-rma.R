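# Reduced major-axis (model-II) regression with bootstrap-over-cases CIs.

#' @noRd
checkXY <- function(x, y, min_n = 3L) {
  if (length(x) != length(y)) phytoStop("'x' and 'y' must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    phytoStop("'x' and 'y' must be finite")
  }
  if (length(x) < min_n) {
    phytoStop(sprintf("need at least %d cases, got %d", min_n, length(x)))
  }
  if (sd(x) == 0 || sd(y) == 0) {
    phytoStop("zero variance in x or y: RMA regression is undefined",
              class = "phytoDegenerateError")
  }
  invisible(NULL)
}

#' Reduced major-axis regression
#'
#' Model-II line for variables that both carry error: the slope is
#' sign(r) * sd(y)/sd(x) with sample (n-1) standard deviations, the
#' intercept passes the line through the centroid, and r is the Pearson
#' correlation. Equals the geometric mean of the OLS(y|x) slope and the
#' reciprocal of the OLS(x|y) slope.
#'
#' @param x,y numeric vectors (n >= 3, both with positive variance).
#' @return an [RMAFit-class] object (confidence intervals unset; see
#'   [bootstrapRmaCi]).
#' @examples
#' fit <- rmaFit(c(0, 1, 2), c(0, 1, 3))
#' coef(fit)  # intercept -0.194, slope 1.528
#' @export
rmaFit <- function(x, y) {
  checkXY(x, y)
  r <- cor(x, y)
  slope <- (if (r < 0) -1 else 1) * sd(y) / sd(x)
  new("RMAFit",
      slope = slope,
      intercept = mean(y) - slope * mean(x),
      pearson_r = r,
      n = length(x))
}

# Vectorised RMA over bootstrap resamples. `idx` is an n x B index matrix;
# returns slope/intercept per column plus a degeneracy mask (resamples whose
# x or y collapsed to a single value).
#' @noRd
rmaBootColumns <- function(x, y, idx) {
  n <- nrow(idx)
  B <- ncol(idx)
  xb <- matrix(x[idx], n, B)
  yb <- matrix(y[idx], n, B)
  degenerate <- (colSums(xb == matrix(xb[1L, ], n, B, byrow = TRUE)) == n) |
                (colSums(yb == matrix(yb[1L, ], n, B, byrow = TRUE)) == n)
  mx <- colMeans(xb)
  my <- colMeans(yb)
  sxx <- colSums(xb * xb) - n * mx * mx
  syy <- colSums(yb * yb) - n * my * my
  sxy <- colSums(xb * yb) - n * mx * my
  sxx[degenerate] <- NA_real_
  slope <- ifelse(sxy < 0, -1, 1) * sqrt(syy / sxx)
  list(slope = slope, intercept = my - slope * mx, degenerate = degenerate)
}

#' Bootstrap-over-cases confidence intervals for an RMA fit
#'
#' Resamples (x_i, y_i) pairs with replacement `n_boot` times and forms
#' percentile (default) or BCa intervals for the RMA slope and intercept.
#' Resamples with zero variance in either variable are redrawn and counted;
#' if more than 10% of draws are degenerate the data are too discrete for a
#' meaningful interval and an instability error is raised. Deterministic for
#' a fixed `seed`; the caller's RNG state is untouched.
#'
#' @param x,y numeric vectors (n >= 3, both with positive variance).
#' @param n_boot bootstrap repetitions (default 2000).
#' @param ci_level confidence level (default 0.95).
#' @param seed integer seed for the resampling stream.
#' @param method `"percentile"` (default) or `"bca"` (bias-corrected and
#'   accelerated, with jackknife acceleration).
#' @return an [RMAFit-class] object with `slope_ci` and `intercept_ci` set.
#' @export
bootstrapRmaCi <- function(x, y, n_boot = 2000L, ci_level = 0.95, seed = 1L,
                           method = c("percentile", "bca")) {
  method <- match.arg(method)
  fit <- rmaFit(x, y)
  stopifnotScalarNumeric(ci_level, "ci_level")
  if (ci_level <= 0 || ci_level >= 1) phytoStop("'ci_level' must be in (0, 1)")
  n_boot <- as.integer(n_boot)
  if (n_boot < 10L) phytoStop("'n_boot' must be at least 10")
  n <- length(x)
  res <- withSeed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
    out <- rmaBootColumns(x, y, idx)
    n_degenerate <- sum(out$degenerate)
    while (any(out$degenerate)) {
      if (n_degenerate > 0.1 * n_boot) {
        phytoStop(sprintf(
          "bootstrap unstable: %d of %d resamples degenerate (> 10%%)",
          n_degenerate, n_boot), class = "phytoInstabilityError")
      }
      bad <- which(out$degenerate)
      idx[, bad] <- sample.int(n, n * length(bad), replace = TRUE)
      redraw <- rmaBootColumns(x, y, idx[, bad, drop = FALSE])
      out$slope[bad] <- redraw$slope
      out$intercept[bad] <- redraw$intercept
      out$degenerate[bad] <- redraw$degenerate
      n_degenerate <- n_degenerate + sum(redraw$degenerate)
    }
    list(slope = out$slope, intercept = out$intercept,
         n_degenerate = n_degenerate)
  })
  alpha <- (1 - ci_level) / 2
  ciOf <- function(stat_boot, stat_hat, jack) {
    if (method == "percentile") {
      return(unname(quantile(stat_boot, c(alpha, 1 - alpha))))
    }
    # BCa: bias correction from the proportion of resamples below the
    # estimate, acceleration from the jackknife skewness.
    z0 <- qnorm(mean(stat_boot < stat_hat))
    if (!is.finite(z0)) z0 <- 0
    jm <- mean(jack)
    num <- sum((jm - jack)^3)
    den <- 6 * (sum((jm - jack)^2))^1.5
    a <- if (den > 0) num / den else 0
    zl <- qnorm(alpha); zu <- qnorm(1 - alpha)
    p <- pnorm(z0 + c(z0 + zl, z0 + zu) / (1 - a * (z0 + c(zl, zu))))
    unname(quantile(stat_boot, p))
  }
  if (method == "bca") {
    jack <- vapply(seq_len(n), function(i) {
      xi <- x[-i]; yi <- y[-i]
      r <- cor(xi, yi)
      s <- (if (r < 0) -1 else 1) * sd(yi) / sd(xi)
      c(s, mean(yi) - s * mean(xi))
    }, numeric(2))
    jack_slope <- jack[1L, ]; jack_int <- jack[2L, ]
  } else {
    jack_slope <- jack_int <- numeric(0)
  }
  initialize(fit,
             ci_level = ci_level,
             slope_ci = ciOf(res$slope, fit@slope, jack_slope),
             intercept_ci = ciOf(res$intercept, fit@intercept, jack_int),
             n_boot = n_boot,
             seed = as.integer(seed),
             n_degenerate = as.integer(res$n_degenerate),
             method = method)
}
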