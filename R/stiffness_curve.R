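#' Piecewise-linear stiffness curve
#'
#' A `stiffness_curve` is a monotone force law defined by ascending strain
#' breakpoints and one non-negative slope per segment, optionally with
#' quadratic smoothing of the slope transition at each interior breakpoint.
#' The force at strain `s` is the integral of the (possibly smoothed) slope
#' over `[0, s]`, so `force(0) = 0` and the force is continuous and
#' non-decreasing.  The abscissa is dimensionless strain for material laws,
#' but the same object is reused in displacement units (m) for lumped series
#' springs; slopes then carry N/m instead of force-per-strain.
#'
#' @param breakpoints Numeric vector of segment start strains, strictly
#'   increasing, first element 0.
#' @param slopes Numeric vector of segment slopes (one per breakpoint; the
#'   last segment extends to infinity).  All slopes must be `>= 0`.
#' @param smoothing_halfwidth Strain half-span over which the slope ramps
#'   linearly from one segment to the next (quadratic blend of the force).
#'   `0` gives an exactly piecewise-linear force.
#' @return An object of class `stiffness_curve`.
#' @examples
#' sk <- stiffness_curve(c(0, 0.4), c(0.1, 18.8), smoothing_halfwidth = 0)
#' evaluate_force(sk, 0.5)   # 0.1*0.4 + 18.8*0.1
#' @export
stiffness_curve <- function(breakpoints, slopes, smoothing_halfwidth = 0.02) {
  breakpoints <- as.numeric(breakpoints)
  slopes <- as.numeric(slopes)
  if (length(breakpoints) == 0L || breakpoints[1] != 0)
    stop("breakpoints must start at 0")
  if (length(breakpoints) > 1L && any(diff(breakpoints) <= 0))
    stop("breakpoints must be strictly increasing")
  if (length(slopes) != length(breakpoints))
    stop("need exactly one slope per segment (length(slopes) == length(breakpoints))")
  if (any(!is.finite(slopes)) || any(slopes < 0))
    stop("slopes must be finite and >= 0")
  if (!is.finite(smoothing_halfwidth) || smoothing_halfwidth < 0)
    stop("smoothing_halfwidth must be >= 0")
  if (length(breakpoints) > 1L) {
    max_hw <- min(diff(breakpoints)) / 2
    if (smoothing_halfwidth > max_hw) smoothing_halfwidth <- max_hw
  }
  cumforce <- if (length(breakpoints) > 1L)
    c(0, cumsum(slopes[-length(breakpoints)] * diff(breakpoints))) else 0
  structure(
    list(breakpoints = breakpoints, slopes = slopes,
         smoothing_halfwidth = smoothing_halfwidth, cumforce = cumforce),
    class = "stiffness_curve"
  )
}

# fast scalar force evaluation (no validation; x assumed finite and >= 0)
.eval_curve <- function(curve, x) {
  bp <- curve$breakpoints
  sl <- curve$slopes
  i <- findInterval(x, bp)
  f <- curve$cumforce[i] + sl[i] * (x - bp[i])
  h <- curve$smoothing_halfwidth
  nb <- length(bp)
  if (h > 0 && nb > 1L) {
    for (j in 2:nb) {
      u <- x - bp[j]
      if (u > -h && u < h) {
        dk <- sl[j] - sl[j - 1L]
        corr <- dk * (u + h)^2 / (4 * h)
        if (u > 0) corr <- corr - dk * u
        f <- f + corr
      }
    }
  }
  f
}

#' @export
print.stiffness_curve <- function(x, ...) {
  cat("<stiffness_curve> ", length(x$slopes), " segment(s), smoothing halfwidth ",
      format(x$smoothing_halfwidth), "\n", sep = "")
  print(data.frame(from = x$breakpoints, slope = x$slopes))
  invisible(x)
}

# cumulative unsmoothed force at the segment breakpoints
.curve_cumforce <- function(curve) curve$cumforce

#' Evaluate the force law of a stiffness curve
#'
#' Integral of the (smoothed) slope from 0 to `strain`.  Monotone
#' non-decreasing and continuous; beyond the last breakpoint the last
#' segment's slope extrapolates linearly.
#'
#' @param curve A [stiffness_curve()].
#' @param strain Numeric vector of strains, all `>= 0`.  Contact sign
#'   handling (compression vs. separation) is the caller's responsibility.
#' @return Force-like values in the curve's force units.
#' @export
evaluate_force <- function(curve, strain) {
  stopifnot(inherits(curve, "stiffness_curve"))
  strain <- as.numeric(strain)
  if (any(!is.finite(strain)) || any(strain < 0))
    stop("strain must be finite and >= 0; handle sign/contact before calling")
  bp <- curve$breakpoints
  sl <- curve$slopes
  cum <- .curve_cumforce(curve)
  idx <- findInterval(strain, bp)          # >= 1 because strain >= 0 = bp[1]
  f <- cum[idx] + sl[idx] * (strain - bp[idx])
  h <- curve$smoothing_halfwidth
  if (h > 0 && length(bp) > 1L) {
    for (j in 2:length(bp)) {
      u <- strain - bp[j]
      inw <- u > -h & u < h
      if (any(inw)) {
        dk <- sl[j] - sl[j - 1L]
        corr <- dk * (u[inw] + h)^2 / (4 * h)
        pos <- u[inw] > 0
        corr[pos] <- corr[pos] - dk * u[inw][pos]
        f[inw] <- f[inw] + corr
      }
    }
  }
  f
}

#' Tangent stiffness (derivative of the force law)
#'
#' Within a segment and outside any smoothing window this equals that
#' segment's slope exactly; inside a smoothing window the slope ramps
#' linearly between the adjacent segment slopes.
#'
#' @inheritParams evaluate_force
#' @return Stiffness values (slope units of the curve).
#' @export
tangent_stiffness <- function(curve, strain) {
  stopifnot(inherits(curve, "stiffness_curve"))
  strain <- as.numeric(strain)
  if (any(!is.finite(strain)) || any(strain < 0))
    stop("strain must be finite and >= 0")
  bp <- curve$breakpoints
  sl <- curve$slopes
  idx <- findInterval(strain, bp)
  k <- sl[idx]
  h <- curve$smoothing_halfwidth
  if (h > 0 && length(bp) > 1L) {
    for (j in 2:length(bp)) {
      u <- strain - bp[j]
      inw <- u > -h & u < h
      if (any(inw)) {
        k[inw] <- sl[j - 1L] + (sl[j] - sl[j - 1L]) * (u[inw] + h) / (2 * h)
      }
    }
  }
  k
}

#' Effective stiffness of two springs in series
#'
#' `k1 * k2 / (k1 + k2)`, always below `min(k1, k2)`.  This is the algebra
#' behind both the instrument-compliance correction of indentation data and
#' the padding-stiffness synthesis.
#'
#' @param k1,k2 Positive stiffnesses (same units, e.g. N/mm).
#' @return The series stiffness in the same units.
#' @examples
#' series_elastic(1.0876, 2.67)
#' @export
series_elastic <- function(k1, k2) {
  if (any(!is.finite(k1)) || any(!is.finite(k2)) || any(k1 <= 0) || any(k2 <= 0))
    stop("series_elastic() requires strictly positive stiffnesses")
  k1 * k2 / (k1 + k2)
}

#' Compose two stiffness curves in series into a displacement-domain curve
#'
#' Two nonlinear springs in series share one force; the total displacement at
#' force F is the sum of the member displacements.  For piecewise-linear
#' members the composed law is again piecewise linear, with breakpoints at
#' the displacements where either member crosses one of its own breakpoints.
#' The returned curve has breakpoints in metres of total compression and
#' slopes in N/m.
#'
#' @param curve1,curve2 [stiffness_curve()] objects in strain units (force in
#'   N per unit strain).
#' @param thickness1,thickness2 Rest thicknesses (m) converting member strain
#'   to member displacement.
#' @return A `stiffness_curve` over displacement (m) with slopes in N/m.  If
#'   both members are all-zero (inert) the zero curve is returned.
#' @export
series_displacement_curve <- function(curve1, thickness1, curve2, thickness2) {
  stopifnot(inherits(curve1, "stiffness_curve"), inherits(curve2, "stiffness_curve"))
  if (thickness1 <= 0 || thickness2 <= 0) stop("rest thicknesses must be > 0")
  if (all(curve1$slopes == 0) || all(curve2$slopes == 0))
    return(stiffness_curve(0, 0, smoothing_halfwidth = 0))
  if (any(curve1$slopes <= 0) || any(curve2$slopes <= 0))
    stop("series composition requires strictly positive slopes on every segment")
  f1 <- .curve_cumforce(curve1)
  f2 <- .curve_cumforce(curve2)
  flev <- sort(unique(c(f1, f2)))
  # displacement of one member at force f (piecewise-linear inverse)
  inv <- function(curve, cum, f) {
    i <- findInterval(f, cum)
    i[i < 1L] <- 1L
    curve$breakpoints[i] + (f - cum[i]) / curve$slopes[i]
  }
  x <- thickness1 * inv(curve1, f1, flev) + thickness2 * inv(curve2, f2, flev)
  n <- length(flev)
  k_last <- 1 / (thickness1 / curve1$slopes[length(curve1$slopes)] +
                 thickness2 / curve2$slopes[length(curve2$slopes)])
  slopes <- if (n > 1L) c(diff(flev) / diff(x), k_last) else k_last
  hw <- max(curve1$smoothing_halfwidth * thickness1,
            curve2$smoothing_halfwidth * thickness2)
  stiffness_curve(x, slopes, smoothing_halfwidth = hw)
}

#' Critically damped viscous coefficient
#'
#' Default damping used where no measured viscosity is available: the
#' critical value `2 * sqrt(k * m)` for a tangent stiffness `k` (N/m) seen by
#' a nodal mass `m` (kg).  Steady-state results do not depend on this choice;
#' it only shapes transients.
#'
#' @param k Tangent stiffness, N/m.
#' @param m Nodal mass, kg.
#' @return Damping coefficient, N s/m.
#' @export
critical_damping <- function(k, m) {
  if (any(k < 0) || any(m <= 0)) stop("need k >= 0 and m > 0")
  2 * sqrt(k * m)
}
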