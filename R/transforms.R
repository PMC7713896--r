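#' Convert a Jaccard index to an uncorrected p-distance
#'
#' Under the k-mer model relating sequence identity to k-mer set overlap,
#' `p = 1 - (2 j / (j + 1))^(1/k)`.  A Jaccard index of exactly zero carries
#' no distance information (any sufficiently diverged pair gives 0) and is
#' returned as `NA`, to be treated as missing downstream.
#'
#' @param j Jaccard index in \[0, 1\] (vectorised).
#' @param k k-mer size used when sketching.
#' @return p-distance in \[0, 1), or `NA` where `j == 0`.
#' @examples
#' p_from_jaccard(0.9, 21)
#' @export
p_from_jaccard <- function(j, k) {
  stopifnot(all(j >= 0 & j <= 1), k >= 1)
  p <- 1 - (2 * j / (j + 1))^(1 / k)
  p[j == 0] <- NA_real_
  p
}

#' Invert a Poisson-corrected distance to a p-distance
#'
#' Tools that report the Poisson-corrected distance `d = -ln(1 - p)` directly
#' (e.g. Mash-style output) are inverted by `p = 1 - exp(-d)`.
#'
#' @param D Non-negative Poisson-corrected distance (vectorised).
#' @return p-distance in \[0, 1).
#' @export
p_from_mash_distance <- function(D) {
  if (any(D < 0)) stop("distance must be non-negative")
  1 - exp(-D)
}

#' Equal-input coefficients from nucleotide composition
#'
#' `b1_from_freqs` computes `b1 = 1 - sum(pi^2)` from one composition vector;
#' `b2_from_freq_pair` computes `b2 = 1 - sum(pi_x * pi_y)` from the two
#' genomes' compositions.  Under equal frequencies both equal 0.75; `b1 = b2`
#' whenever the two compositions coincide.
#'
#' @param freqs,fx,fy A/C/G/T frequency vectors summing to 1.
#' @return Scalar coefficient in \[0, 1\].
#' @examples
#' b1_from_freqs(c(0.25, 0.25, 0.25, 0.25))  # 0.75
#' @export
b1_from_freqs <- function(freqs) {
  .check_freqs(freqs)
  1 - sum(freqs^2)
}

#' @rdname b1_from_freqs
#' @export
b2_from_freq_pair <- function(fx, fy) {
  .check_freqs(fx)
  .check_freqs(fy)
  1 - sum(fx * fy)
}

.check_freqs <- function(freqs) {
  if (length(freqs) != 4L || anyNA(freqs) || any(freqs < 0))
    stop("frequencies must be a valid A/C/G/T vector")
  if (abs(sum(freqs) - 1) > 1e-8)
    stop("frequencies must sum to 1 (got ", format(sum(freqs)), ")")
  invisible(freqs)
}

#' Logarithmic distance transformations (Poisson correction / equal input)
#'
#' `ei_log_distance` computes `d = -b1 ln(1 - p / b2)`; with `b1 = b2 = 1`
#' this is the Poisson correction, with composition-derived coefficients the
#' equal-input (F81) distance.  `p >= b2` lies outside the model and yields
#' `NA` (missing), as does a missing `p`.
#'
#' @param p p-distance(s) in \[0, 1).
#' @param b1,b2 Equal-input coefficients (see [b1_from_freqs()]); both 1 for
#'   the Poisson correction.
#' @return Evolutionary distance(s) in substitutions per site; `NA` where the
#'   transformation is undefined.
#' @examples
#' ei_log_distance(0.1)                     # Poisson correction
#' ei_log_distance(0.3, 0.75, 0.75)         # equal input, f1 composition
#' @export
ei_log_distance <- function(p, b1 = 1, b2 = 1) {
  stopifnot(b1 > 0, b1 <= 1, b2 > 0, b2 <= 1)
  d <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p >= 0 & p < b2
  d[ok] <- -b1 * log(1 - p[ok] / b2)
  d
}

#' Equal-input distance with Gamma rate heterogeneity
#'
#' `d = a b1 ((1 - p / b2)^(-1/a) - 1)`, where `a` is the shape of the Gamma
#' distribution of substitution rates (mean 1) across sites; small `a` means
#' strong heterogeneity.  As `a` grows this converges to [ei_log_distance()],
#' and `a = Inf` dispatches to it exactly.  Under the equal-frequency
#' sub-model (`b1 = b2 = 0.75`) it is the exact inverse of the Jukes-Cantor
#' + Gamma expected p-distance.
#'
#' @inheritParams ei_log_distance
#' @param a Gamma shape parameter, positive; `Inf` for rate homogeneity.
#' @return Evolutionary distance(s); `NA` where `p >= b2` or `p` is missing.
#' @examples
#' ei_gamma_distance(0.3, a = 1, b1 = 0.75, b2 = 0.75)  # 0.5
#' @export
ei_gamma_distance <- function(p, a, b1 = 1, b2 = 1) {
  stopifnot(a > 0)
  if (is.infinite(a)) return(ei_log_distance(p, b1, b2))
  stopifnot(b1 > 0, b1 <= 1, b2 > 0, b2 <= 1)
  d <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p >= 0 & p < b2
  d[ok] <- a * b1 * ((1 - p[ok] / b2)^(-1 / a) - 1)
  d
}

#' Legacy double-log transformation
#'
#' The transformation `delta = -b1 ln(1 + ln(1 - p) / b2)` arises when an
#' equal-input correction is applied to a value that is already
#' Poisson-corrected (a historical mis-reading of Mash-style output as a raw
#' p-distance).  It is well approximated on `p <= 0.35` by
#' [ei_gamma_distance()] with a shape near 1.2, which [fit_equiv_a()]
#' quantifies.
#'
#' @inheritParams ei_log_distance
#' @return Distance(s); `NA` where `1 + ln(1 - p)/b2 <= 0`.
#' @export
delta_v11 <- function(p, b1 = 1, b2 = 1) {
  stopifnot(b1 > 0, b1 <= 1, b2 > 0, b2 <= 1)
  inner <- 1 + log(1 - p) / b2
  d <- rep(NA_real_, length(p))
  ok <- !is.na(inner) & inner > 0
  d[ok] <- -b1 * log(inner[ok])
  d
}

#' Fit the Gamma-shape equivalence parameter
#'
#' Finds the shape `a` for which the Gamma equal-input transformation
#' [ei_gamma_distance()] best matches a target p-to-d relationship in the
#' least-squares sense.  The target may be a function `p -> d`, or observed
#' pairs supplied as `p`/`d` vectors (in which case the grid arguments are
#' ignored and the fit runs over the pairs).  Minimisation is bracketed
#' scalar optimisation on `log(a)` over \[ln 0.01, ln 100\] and is
#' deterministic given the grid.
#'
#' @param target Function mapping p-distance to distance, or numeric vector
#'   of observed distances `d` when `p` is given.
#' @param b1,b2 Equal-input coefficients of the fitted transformation.
#' @param p Optional vector of p-distances paired with numeric `target`.
#' @param p_grid Evaluation grid when `target` is a function; defaults to
#'   `(0, 0.35]` in steps of 0.001, the validity range of sketch-based
#'   p-distance estimates.
#' @return Fitted shape `a` (scalar), with the attained sum of squares in
#'   attribute `"sse"`.
#' @examples
#' fit_equiv_a(function(p) ei_gamma_distance(p, 0.5, 0.75, 0.75),
#'             b1 = 0.75, b2 = 0.75)  # recovers 0.5
#' @export
fit_equiv_a <- function(target, b1, b2, p = NULL,
                        p_grid = seq(0.001, 0.35, by = 0.001)) {
  if (is.function(target)) {
    stopifnot(all(p_grid > 0), all(p_grid < b2))
    pp <- p_grid
    dd <- target(p_grid)
  } else {
    stopifnot(is.numeric(target), !is.null(p), length(p) == length(target))
    keep <- !is.na(p) & !is.na(target) & p > 0 & p < b2
    pp <- p[keep]
    dd <- target[keep]
  }
  if (!all(is.finite(dd))) stop("target distances must be finite on the grid")
  sse <- function(loga) {
    fit <- ei_gamma_distance(pp, exp(loga), b1, b2)
    sum((fit - dd)^2)
  }
  opt <- optimize(sse, interval = log(c(0.01, 100)), tol = 1e-10)
  structure(exp(opt$minimum), sse = opt$objective)
}
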