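#' Plate load case for the quasi-static interface-design model
#'
#' External loading on a rigid attachment plate of length `L`, reduced by
#' transmissibility to an equivalent normal force `F_L` and moment `M_L` at
#' the plate centre, plus the strap bias force `F_b` (also at the centre).
#' Sign convention: positions run along the plate with the origin at its
#' centre; a positive (counter-clockwise) `M_L` shifts the high-pressure
#' region toward positive x, and the first moment of the reaction pressure
#' about the centre equals `M_L`.
#'
#' @param F_L External force, normal component, N.
#' @param M_L External moment at the plate centre, N m (CCW positive).
#' @param F_b Strap bias force, N.
#' @param L Plate length, m.
#' @return A `plate_load_case`.
#' @export
plate_load_case <- function(F_L, M_L = 0, F_b = 0, L) {
  if (L <= 0) stop("plate length L must be > 0")
  if (F_L + F_b < 0) stop("net normal load F_L + F_b must be >= 0")
  structure(list(F_L = F_L, M_L = M_L, F_b = F_b, L = L),
            class = "plate_load_case")
}

#' Pressure profile along an attachment plate
#'
#' @param positions Positions along the plate, m from the plate centre.
#' @param pressures Line pressures, N/m (divide by plate width for Pa),
#'   all `>= 0`.
#' @param region_boundary,peak Optional analytic annotations.
#' @return A `pressure_profile`.
#' @export
pressure_profile <- function(positions, pressures, region_boundary = NA_real_,
                             peak = NULL) {
  if (length(positions) != length(pressures))
    stop("positions and pressures must have equal length")
  if (any(pressures < -1e-12)) stop("pressures must be >= 0")
  pressures <- pmax(pressures, 0)
  structure(list(positions = positions, pressures = pressures,
                 region_boundary = region_boundary,
                 peak = if (is.null(peak)) max(pressures) else peak),
            class = "pressure_profile")
}

#' Peak-pressure comfort cost
#'
#' The discomfort cost of a pressure distribution is its maximum, following
#' the pain-pressure-threshold rationale: comfort is limited by the most
#' loaded point, not the average.
#'
#' @param profile A [pressure_profile()].
#' @return Peak line pressure, N/m.
#' @export
peak_pressure_cost <- function(profile) {
  stopifnot(inherits(profile, "pressure_profile"))
  max(profile$pressures)
}

#' Analytic minimum-peak-pressure distribution
#'
#' For a rigid plate loaded by net normal force `F_L + F_b` and moment
#' `M_L`, the distribution minimising peak pressure subject to force and
#' moment balance consists of two uniform regions.  The centre of the
#' high-pressure region sits at `x = M_L / (F_L + F_b)` and its magnitude is
#' `P_peak = (F_L + F_b) / (L - 2 x)`; the remaining region carries the
#' (possibly zero) uniform pressure needed to close the force balance.
#' With `M_L = 0` the distribution degenerates to uniform pressure
#' `(F_L + F_b) / L`; negating `M_L` mirrors the profile.
#'
#' @param case A [plate_load_case()].
#' @param n Number of evaluation points for the returned sampled profile.
#' @return A [pressure_profile()] with `peak`, `region_boundary` (the edge
#'   of the high region) and sampled pressures.
#' @export
analytic_optimum <- function(case, n = 201) {
  stopifnot(inherits(case, "plate_load_case"))
  Ft <- case$F_L + case$F_b
  L <- case$L
  if (Ft <= 0) stop("net normal load must be > 0 for a pressure distribution")
  ml <- case$M_L
  mir <- ml < 0                      # solve for CCW moment, mirror after
  ml <- abs(ml)
  x <- ml / Ft
  if (x >= L / 2)
    stop("infeasible load case: no non-negative pressure distribution can ",
         "balance this moment; increase the bias force F_b ",
         "(x = M_L/(F_L+F_b) must be < L/2)")
  p_peak <- Ft / (L - 2 * x)
  # high region spans [2x - L/2, L/2] (width L - 2x, centred on x); the
  # remaining region carries zero pressure at the optimum
  bnd <- 2 * x - L / 2
  pos <- seq(-L / 2, L / 2, length.out = n)
  pr <- ifelse(pos >= bnd, p_peak, 0)
  if (mir) {
    pr <- rev(pr)
    bnd <- -bnd
  }
  pressure_profile(pos, pr, region_boundary = bnd, peak = p_peak)
}

#' Minimal bias force for a non-negative optimal pressure distribution
#'
#' The lowest strap bias that keeps the low-pressure region of the optimal
#' two-region distribution non-negative: `F_b = 4 |M_L| / L - F_L`, clamped
#' at zero.  At exactly this bias the low region carries zero pressure, and
#' a grid search of peak pressure over `F_b` attains its minimum here.
#'
#' @param F_L External normal force, N.
#' @param M_L External moment, N m.
#' @param L Plate length, m.
#' @return Optimal bias force, N.
#' @export
optimal_bias_force <- function(F_L, M_L, L) {
  if (L <= 0) stop("plate length L must be > 0")
  max(0, 4 * abs(M_L) / L - F_L)
}

#' Symmetric linear effective-stiffness profile
#'
#' Per-point effective stiffness of the discretised interface: highest at
#' the plate centre (`k_mid`), tapering linearly and symmetrically to
#' `k_edge` at each edge.  Parameterised by the mean stiffness `k_mean` and
#' the gradient `g = (k_mid - k_edge) / (L / 2)` so that total compliance is
#' comparable across a gradient sweep.
#'
#' @param k_mean Mean stiffness, N/mm.
#' @param gradient Stiffness gradient, N/mm per m of distance from centre.
#' @param L Plate length, m.
#' @param n_points Number of discrete contact points (default 15).
#' @return A `stiffness_profile` with per-point positions (m) and `k_eff`
#'   (N/mm).
#' @export
stiffness_profile <- function(k_mean, gradient = 0, L, n_points = 15) {
  if (k_mean <= 0) stop("k_mean must be > 0")
  if (gradient < 0) stop("gradient must be >= 0 (taper from centre to edge)")
  if (n_points < 3) stop("need at least 3 contact points")
  if (L <= 0) stop("plate length L must be > 0")
  k_mid <- k_mean + gradient * L / 4
  k_edge <- k_mean - gradient * L / 4
  if (k_edge <= 0)
    stop("gradient too steep: k_edge would be <= 0 (need gradient < 4*k_mean/L)")
  s <- L / n_points
  pos <- (seq_len(n_points) - (n_points + 1) / 2) * s
  k_eff <- k_mid - gradient * abs(pos)
  structure(list(k_mid = k_mid, k_edge = k_edge, k_mean = k_mean,
                 gradient = gradient, L = L, n_points = n_points,
                 spacing = s, positions = pos, k_eff = k_eff),
            class = "stiffness_profile")
}

#' Per-point stiffness profile from measured values
#'
#' @param positions Positions along the plate, m from centre.
#' @param k_eff Effective stiffnesses, N/mm, all `> 0`.
#' @param L Plate length, m; default spans the points.
#' @return A `stiffness_profile` (gradient reported as the fitted linear
#'   taper).
#' @export
stiffness_profile_from_points <- function(positions, k_eff, L = NULL) {
  if (length(positions) != length(k_eff) || length(k_eff) < 2)
    stop("need >= 2 matched positions and stiffnesses")
  if (any(k_eff <= 0)) stop("k_eff must be > 0")
  n <- length(k_eff)
  if (is.null(L)) L <- diff(range(positions)) * n / (n - 1)
  fit <- stats::lm(k_eff ~ I(abs(positions)))
  structure(list(k_mid = max(k_eff), k_edge = min(k_eff),
                 k_mean = mean(k_eff),
                 gradient = max(0, -unname(stats::coef(fit)[2])),
                 L = L, n_points = n, spacing = L / n,
                 positions = positions, k_eff = k_eff),
            class = "stiffness_profile")
}

#' Rigid-plate equilibrium on a bed of unilateral springs
#'
#' Solves the quasi-static equilibrium of a rigid plate resting on
#' `n_points` discrete springs (effective stiffness `k_eff` in N/mm at each
#' point, tributary spacing `L / n_points`), loaded by the net normal force
#' `F_L + F_b` and moment `M_L`.  The two unknowns are the plate's normal
#' translation and tilt; springs whose point would be in tension are
#' released (unilateral contact) and the 2x2 balance re-solved on the
#' active set until it is consistent.
#'
#' @param profile A [stiffness_profile()].
#' @param case A [plate_load_case()] with matching `L`.
#' @return List: `profile` (a [pressure_profile()] of per-point line
#'   pressures), `forces` (per-point N), `relative_displacement` (m, the
#'   largest displacement of the plate into the tissue, i.e. translation
#'   plus the tilt contribution at the deepest edge), `translation` (m),
#'   `tilt` (rad), `active` (logical).
#' @export
simulate_discrete_interface <- function(profile, case) {
  stopifnot(inherits(profile, "stiffness_profile"),
            inherits(case, "plate_load_case"))
  if (abs(profile$L - case$L) > 1e-12)
    stop("profile and load case disagree on plate length")
  Ft <- case$F_L + case$F_b
  ml <- case$M_L
  x <- profile$positions
  k <- profile$k_eff * 1e3                  # N/m per point
  active <- rep(TRUE, profile$n_points)
  for (iter in seq_len(profile$n_points + 1L)) {
    ka <- k * active
    S0 <- sum(ka); S1 <- sum(ka * x); S2 <- sum(ka * x^2)
    det <- S0 * S2 - S1^2
    if (S0 <= 0 || det <= 0)
      stop("no equilibrium: all contact points released")
    w <- (S2 * Ft - S1 * ml) / det
    phi <- (S0 * ml - S1 * Ft) / det
    u <- w + phi * x
    newly <- active & (u < 0)
    if (!any(newly)) break
    active[newly] <- FALSE
  }
  f <- ifelse(active, k * pmax(u, 0), 0)
  pr <- pressure_profile(x, f / profile$spacing)
  list(profile = pr, forces = f,
       relative_displacement = w + abs(phi) * profile$L / 2,
       translation = w, tilt = phi, active = active)
}

#' Sweep bias force and stiffness gradient
#'
#' Evaluates the discrete interface over a grid of strap bias forces and
#' stiffness-profile gradients at fixed external load, recording peak
#' pressure and relative displacement -- the comfort/accuracy trade-off
#' surface.
#'
#' @param F_b_grid Bias forces, N.
#' @param gradient_grid Stiffness gradients, N/mm per m.
#' @param case Base [plate_load_case()] (its `F_b` is replaced by the grid).
#' @param k_mean Mean effective stiffness, N/mm.
#' @param n_points Contact points per plate.
#' @return Data frame `(F_b_n, gradient_n_mm_per_m, M_L_nm, peak_pressure_n_m,
#'   relative_displacement_mm, force_balance_rel_err, moment_balance_rel_err)`.
#' @export
design_sweep <- function(F_b_grid, gradient_grid, case, k_mean = 1.0876,
                         n_points = 15) {
  if (!length(F_b_grid) || !length(gradient_grid))
    stop("sweep grids must be non-empty")
  rows <- list()
  for (Fb in F_b_grid) for (g in gradient_grid) {
    cs <- plate_load_case(case$F_L, case$M_L, Fb, case$L)
    sp <- stiffness_profile(k_mean, g, case$L, n_points)
    eq <- simulate_discrete_interface(sp, cs)
    Ft <- cs$F_L + cs$F_b
    fb_err <- abs(sum(eq$forces) - Ft) / max(Ft, 1e-12)
    mb_err <- abs(sum(eq$forces * sp$positions) - cs$M_L) /
      max(abs(cs$M_L), 1e-9)
    rows[[length(rows) + 1L]] <- data.frame(
      F_b_n = Fb, gradient_n_mm_per_m = g, M_L_nm = cs$M_L,
      peak_pressure_n_m = peak_pressure_cost(eq$profile),
      relative_displacement_mm = eq$relative_displacement * 1e3,
      force_balance_rel_err = fb_err, moment_balance_rel_err = mb_err)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Padding stiffness achieving a target effective stiffness
#'
#' Given the target effective stiffness `k_eff` of the series
#' dorsum-plus-padding stack and the measured dorsum stiffness `k_dorsum`,
#' the padding must provide
#' `k_pHRI = k_eff * k_dorsum / (k_dorsum - k_eff)`, the algebraic inverse
#' of the series coupling: `series_elastic(k_pHRI, k_dorsum) == k_eff`.
#'
#' @param k_eff Target effective stiffness, N/mm; must satisfy
#'   `0 < k_eff < k_dorsum`.
#' @param k_dorsum Measured dorsum stiffness, N/mm.
#' @return Required padding stiffness, N/mm.
#' @export
padding_stiffness <- function(k_eff, k_dorsum) {
  if (any(k_eff <= 0) || any(k_dorsum <= 0))
    stop("stiffnesses must be > 0")
  if (any(k_eff >= k_dorsum))
    stop("infeasible target: k_eff must be below k_dorsum ",
         "(the dorsum alone is softer than the requested series stiffness)")
  k_eff * k_dorsum / (k_dorsum - k_eff)
}
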