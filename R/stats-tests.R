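# Correlation, OLS, rank-based group comparison and chlorophyll binning.

#' Pearson correlation with two-sided t-test
#'
#' Product-moment correlation; the p-value comes from the t transform with
#' n - 2 degrees of freedom (via [stats::cor.test]).
#'
#' @param x,y finite numeric vectors, n >= 3, positive variance.
#' @return list with `r`, `p` (two-sided) and `n`.
#' @export
pearsonTest <- function(x, y) {
  checkXY(x, y)
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Ordinary least squares of y on x
#'
#' Model-I fit used where only the response carries error (or, as in the
#' RSI-stratified temperature fits, where a null slope is the question);
#' two-sided t-test on the slope.
#'
#' @param x,y finite numeric vectors, n >= 3; x with positive variance.
#' @return list with `slope`, `intercept`, `p_slope`, `r2` and `n`.
#' @export
olsFit <- function(x, y) {
  if (length(x) != length(y)) phytoStop("'x' and 'y' must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y))) phytoStop("inputs must be finite")
  if (length(x) < 3L) phytoStop("need at least 3 cases")
  if (sd(x) == 0) {
    phytoStop("zero variance in x: OLS slope undefined",
              class = "phytoDegenerateError")
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)$coefficients
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       p_slope = if (nrow(sm) == 2L && ncol(sm) == 4L) sm[2L, 4L] else NA_real_,
       r2 = summary(fit)$r.squared,
       n = length(x))
}

#' Mann-Whitney U test between two groups
#'
#' Standard two-sided rank-sum test (the named test compares distributions
#' through ranks, not means, loose usage notwithstanding). The U statistic
#' is counted for group `a` with midranks for ties. The p-value is exact by
#' enumeration when n_a * n_b <= 400 and the pooled data are tie-free, and
#' otherwise uses the normal approximation with tie and continuity
#' corrections (delegated to [stats::wilcox.test]).
#'
#' @param a,b numeric vectors, each with at least 2 observations.
#' @param a_label,b_label group labels carried into the result.
#' @return data.frame row with `group_a, group_b, u_statistic, p_value,
#'   n_a, n_b`.
#' @export
mannWhitney <- function(a, b, a_label = "a", b_label = "b") {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L || anyNA(a) || anyNA(b)) {
    phytoStop("both groups need at least 2 non-missing observations")
  }
  pooled <- c(a, b)
  ties <- anyDuplicated(pooled) > 0L
  exact <- !ties && length(a) * length(b) <= 400L
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                     exact = exact, correct = TRUE))
  data.frame(group_a = a_label, group_b = b_label,
             u_statistic = unname(wt$statistic),
             p_value = min(1, wt$p.value),
             n_a = length(a), n_b = length(b),
             stringsAsFactors = FALSE)
}

.defaultChlEdges <- c(0, 0.2, 0.5, 2, 5, Inf)

#' @noRd
chlBinLabels <- function(edges) {
  k <- length(edges) - 1L
  lab <- character(k)
  for (i in seq_len(k)) {
    lab[i] <- if (is.infinite(edges[i + 1L])) sprintf(">%g", edges[i])
              else sprintf("%g-%g", edges[i], edges[i + 1L])
  }
  lab
}

#' Group stations into chlorophyll a concentration bins
#'
#' Assigns each station to exactly one bin using right-open intervals
#' [lo, hi) - a station at an edge falls into the upper bin - with the last
#' bin open-ended. Returns per-bin membership and the mean and sd of the
#' biomass turnover rate \eqn{P^C}.
#'
#' @param chl_a chlorophyll a concentrations, mg m\eqn{^{-3}} (> 0).
#' @param p_c biomass turnover rates, d\eqn{^{-1}}, same length.
#' @param edges bin edges (default 0, 0.2, 0.5, 2, 5, Inf).
#' @return list with `assignment` (factor over the bin labels) and `summary`
#'   (data.frame `bin, n, mean_pc, sd_pc`).
#' @export
binByChl <- function(chl_a, p_c, edges = .defaultChlEdges) {
  if (length(chl_a) != length(p_c)) phytoStop("inputs must have equal length")
  if (any(!is.finite(chl_a)) || any(chl_a <= 0)) {
    phytoStop("'chl_a' must be positive and finite", class = "phytoDomainError")
  }
  if (is.unsorted(edges, strictly = TRUE)) phytoStop("'edges' must be increasing")
  labels <- chlBinLabels(edges)
  assignment <- cut(chl_a, breaks = edges, labels = labels,
                    right = FALSE, include.lowest = FALSE)
  summ <- do.call(rbind, lapply(labels, function(lb) {
    sel <- assignment == lb
    data.frame(bin = lb, n = sum(sel),
               mean_pc = if (any(sel)) mean(p_c[sel]) else NA_real_,
               sd_pc = if (sum(sel) > 1L) sd(p_c[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(assignment = assignment, summary = summ)
}
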