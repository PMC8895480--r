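#' Force transmitted by one contact unit
#'
#' Evaluates the series tissue + padding unit at the current node state.
#' The normal direction carries the series elastic force at the current
#' compression plus the series viscous force, clamped at zero: the unit is
#' unilateral and can only push.  When the clamp engages (for instance on
#' rapid withdrawal of loading, where the viscous term would otherwise drive
#' the normal force negative) the unit is `lifted` and transmits no
#' tangential force either.  Normal and tangential strains are orthogonal
#' and evaluated independently.
#'
#' @param unit A contact unit as stored in `system$phrii_units`.
#' @param node_pos,node_vel Length-2 node position (m) and velocity (m/s).
#' @param anchor_pos,anchor_vel Length-2 world-frame anchor state; defaults
#'   to the unit's static anchor.
#' @return List with `force` (2-vector, N, acting on the node), scalars
#'   `normal_force` and `tangential_force` (N), the compression `delta` (m;
#'   negative = open gap) and logical `in_contact`.
#' @export
phrii_force <- function(unit, node_pos, node_vel,
                        anchor_pos = unit$ground_anchor,
                        anchor_vel = c(0, 0)) {
  nrm <- unit$contact_normal
  tng <- c(-nrm[2], nrm[1])
  dp <- node_pos - anchor_pos
  dv <- node_vel - anchor_vel
  gap <- sum(dp * nrm)
  delta <- unit$rest_thickness - gap      # > 0 while compressed
  if (unit$inert)
    return(list(force = c(0, 0), normal_force = 0, tangential_force = 0,
                delta = delta, in_contact = FALSE))
  ddot <- -sum(dv * nrm)                  # compression rate
  f_el <- if (delta > 0) .eval_curve(unit$normal_curve, delta) else 0
  fn_raw <- f_el + unit$damping_normal * ddot
  in_contact <- delta > 0 && fn_raw > 0
  fn <- if (in_contact) fn_raw else 0
  ft <- 0
  if (in_contact) {
    u <- sum(dp * tng) - unit$tangential_offset
    udot <- sum(dv * tng)
    f_tan_el <- if (abs(u) > 0)
      sign(u) * .eval_curve(unit$tangential_curve, abs(u)) else 0
    ft <- -(f_tan_el + unit$damping_tangential * udot)
    if (is.finite(unit$tangential_cap))
      ft <- max(-unit$tangential_cap, min(unit$tangential_cap, ft))
  }
  list(force = nrm * fn + tng * ft, normal_force = fn, tangential_force = ft,
       delta = delta, in_contact = in_contact)
}

# axial force of an elastic link given endpoint states; positive = tension
.link_axial_force <- function(link, pa, pb, va, vb) {
  d <- pb - pa
  len <- sqrt(sum(d^2))
  if (len < 1e-12) return(list(force_on_a = c(0, 0), tension = 0))
  axis <- d / len
  strain <- (len - link$rest_length) / link$rest_length + link$strain_offset
  f_el <- if (strain >= 0) .eval_curve(link$stiffness_curve, strain)
          else -.eval_curve(link$stiffness_curve, -strain)
  ldot <- sum((vb - va) * axis)
  tension <- link$pretension + f_el + link$damping * ldot
  if (link$tension_only && tension < 0) tension <- 0
  list(force_on_a = axis * tension, tension = tension)
}
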