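#' Through-origin regression of estimated on true p-distances
#'
#' Fits `p_hat = beta * p` by least squares through the origin over the
#' subset with `p <= p_max`, excluding pairs whose estimate is missing
#' (zero Jaccard index).  `beta = sum(p * p_hat) / sum(p^2)`; the
#' coefficient of determination uses the uncentered total sum of squares of
#' the no-intercept fit.
#'
#' @param p True p-distances.
#' @param p_hat Estimated p-distances; `NA` marks a zero-Jaccard estimate.
#' @param p_max Upper truncation of the regression subset.
#' @return List with `beta`, `r2` and `n` (pairs used).
#' @export
origin_regression <- function(p, p_hat, p_max = Inf) {
  stopifnot(length(p) == length(p_hat))
  keep <- !is.na(p_hat) & p <= p_max
  if (sum(keep) < 2L) stop("fewer than 2 usable pairs below p_max")
  x <- p[keep]; y <- p_hat[keep]
  beta <- sum(x * y) / sum(x^2)
  r2 <- 1 - sum((y - beta * x)^2) / sum(y^2)
  list(beta = beta, r2 = r2, n = sum(keep))
}

#' Fisher z-test that a correlation exceeds a threshold
#'
#' One-sided test of `rho > rho0` via the Fisher transformation:
#' `z = (atanh(r) - atanh(rho0)) * sqrt(n - 3)`, compared to a standard
#' normal.  Correlations at +-1 are clipped to `1 - 1e-12` before the
#' transform.
#'
#' @param r Observed Pearson correlation.
#' @param n Sample size (>= 4).
#' @param rho0 Threshold correlation (default 0.99).
#' @param alpha Significance level (default 0.01).
#' @return `TRUE` iff the one-sided p-value is below `alpha`.
#' @export
fisher_r_exceeds <- function(r, n, rho0 = 0.99, alpha = 0.01) {
  stopifnot(n >= 4, abs(r) <= 1)
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  z <- (atanh(r) - atanh(rho0)) * sqrt(n - 3)
  (1 - pnorm(z)) < alpha
}

#' Highest p-distance with confirmed near-perfect correlation
#'
#' Scans a grid of truncation values `p_max`; for each, the pairs with
#' `p <= p_max` (excluding missing estimates) are tested for Pearson
#' correlation significantly above `rho0` via [fisher_r_exceeds()].  Returns
#' the largest passing grid value (0 if none).  Grid points with fewer than
#' 4 usable pairs are skipped.
#'
#' @inheritParams origin_regression
#' @param grid Increasing truncation values (default 0.10 to 0.55 by 0.005).
#' @param rho0,alpha Passed to [fisher_r_exceeds()].
#' @return Scalar: the highest qualifying truncation, or 0.
#' @export
find_p_r99 <- function(p, p_hat, grid = seq(0.10, 0.55, by = 0.005),
                       rho0 = 0.99, alpha = 0.01) {
  stopifnot(!is.unsorted(grid))
  best <- 0
  for (pm in grid) {
    keep <- !is.na(p_hat) & p <= pm
    if (sum(keep) < 4L) next
    r <- cor(p[keep], p_hat[keep])
    if (!is.na(r) && fisher_r_exceeds(r, sum(keep), rho0, alpha)) best <- pm
  }
  best
}

#' Cumulative fraction of zero-Jaccard estimates
#'
#' Fraction of pairs with `p <= p_max` whose Jaccard estimate was zero
#' (coded `NA` in `p_hat`).
#'
#' @inheritParams origin_regression
#' @return Fraction in \[0, 1\].
#' @export
f_zero_j <- function(p, p_hat, p_max = Inf) {
  keep <- p <= p_max
  if (!any(keep)) return(0)
  mean(is.na(p_hat[keep]))
}

#' Accuracy report for a set of (p, p_hat) observations
#'
#' Bundles the benchmark statistics: through-origin slope and R-squared,
#' Pearson correlation, the highest truncation with confirmed r > rho0, and
#' the cumulative zero-Jaccard fraction.
#'
#' @inheritParams find_p_r99
#' @param p_max Truncation for the regression statistics.
#' @return Object of class `accuracy_report`.
#' @export
accuracy_report <- function(p, p_hat, p_max = Inf,
                            grid = seq(0.10, 0.55, by = 0.005)) {
  reg <- origin_regression(p, p_hat, p_max)
  keep <- !is.na(p_hat) & p <= p_max
  structure(list(beta = reg$beta, r2 = reg$r2,
                 r = cor(p[keep], p_hat[keep]), n = reg$n,
                 p_max = p_max, p_r99 = find_p_r99(p, p_hat, grid),
                 f_zero_j = f_zero_j(p, p_hat, p_max)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("Sketch p-distance accuracy report\n")
  cat(sprintf("  n = %d (p <= %.3g), beta = %.4f, R2 = %.5f, r = %.5f\n",
              x$n, x$p_max, x$beta, x$r2, x$r))
  cat(sprintf("  p_r>0.99 = %.3f, f(j=0) = %.4f\n", x$p_r99, x$f_zero_j))
  invisible(x)
}

#' Percentage of exactly recovered reference topologies
#'
#' Compares inferred and reference trees slot by slot; a slot counts as
#' recovered when the unrooted Robinson-Foulds distance is zero.
#'
#' @param inferred,reference Lists of `ape::phylo` trees of equal length;
#'   slot `i` of both must share a leaf set.
#' @return Percentage in \[0, 100\].
#' @export
recovery_percentage <- function(inferred, reference) {
  stopifnot(length(inferred) == length(reference), length(inferred) >= 1)
  hits <- vapply(seq_along(inferred), function(i) {
    if (!setequal(inferred[[i]]$tip.label, reference[[i]]$tip.label))
      stop("leaf sets differ in slot ", i)
    rf_distance(inferred[[i]], reference[[i]]) == 0
  }, logical(1))
  100 * mean(hits)
}
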