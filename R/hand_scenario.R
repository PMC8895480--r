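#' Hand-dorsum exoskeleton geometry
#'
#' Geometry of the two-plate dorsal attachment: a 50 mm metacarpal plate and
#' a 30 mm proximal-phalanx plate with 10 mm straps, separated by a small
#' gap at the MCP joint.  Coordinates: x distal (away from the wrist), y
#' dorsal (out of the back of the hand), MCP at the origin; the bone dorsal
#' surface is the line y = 0 and the phalanx-side anchors live in a ground
#' frame rotated about the MCP by `mcp_angle`.
#'
#' @param metacarpal_plate_length,phalanx_plate_length Plate lengths, m.
#' @param strap_width Strap width, m (used to convert line pressure to Pa).
#' @param plate_gap Half-gap between each plate edge and the MCP, m.
#' @param tissue_thickness_dorsal,tissue_thickness_palmar Soft-tissue
#'   thicknesses, m.
#' @param padding_thickness Device padding thickness, m.
#' @param apex_standoff Height of each plate's apex (non-contacting) node
#'   above the plate line, m.
#' @param mcp_angle MCP joint angle, rad (0 = straight finger).
#' @param node_mass Node mass, kg (steady-state results are mass-independent).
#' @return A `hand_geometry` list.
#' @export
hand_geometry <- function(metacarpal_plate_length = 0.050,
                          phalanx_plate_length = 0.030,
                          strap_width = 0.010,
                          plate_gap = 0.003,
                          tissue_thickness_dorsal = 0.006,
                          tissue_thickness_palmar = 0.012,
                          padding_thickness = 0.003,
                          apex_standoff = 0.005,
                          mcp_angle = 0,
                          node_mass = 0.005) {
  g <- list(metacarpal_plate_length = metacarpal_plate_length,
            phalanx_plate_length = phalanx_plate_length,
            strap_width = strap_width, plate_gap = plate_gap,
            tissue_thickness_dorsal = tissue_thickness_dorsal,
            tissue_thickness_palmar = tissue_thickness_palmar,
            padding_thickness = padding_thickness,
            apex_standoff = apex_standoff, mcp_angle = mcp_angle,
            node_mass = node_mass)
  lens <- c(metacarpal_plate_length, phalanx_plate_length, strap_width,
            plate_gap, tissue_thickness_dorsal, tissue_thickness_palmar,
            padding_thickness, apex_standoff, node_mass)
  if (any(lens <= 0)) stop("hand geometry lengths and mass must be > 0")
  structure(g, class = "hand_geometry")
}

#' Hand-scenario material set
#'
#' Lumped per-contact-point stiffnesses in N/mm.  The dorsal tissue default
#' is the measured mean hand-dorsum stiffness; tissue laws stiffen
#' progressively with strain (elastin-to-collagen style nonlinearity), which
#' is what makes angular displacement fall with strap pretension.
#'
#' @param dorsal_tissue_k,palmar_tissue_k,padding_k Baseline stiffnesses,
#'   N/mm per contact point.
#' @param strap_k Strap axial stiffness, N/mm.
#' @param linkage_k Inter-plate exoskeleton linkage compliance, N/mm.
#' @param tangential_ratio Tangential / normal stiffness ratio of tissue and
#'   padding.
#' @return A `hand_materials` list.
#' @export
hand_materials <- function(dorsal_tissue_k = 1.0876, palmar_tissue_k = 3,
                           padding_k = 2.0, strap_k = 20, linkage_k = 10,
                           tangential_ratio = 0.5) {
  if (any(c(dorsal_tissue_k, palmar_tissue_k, padding_k, strap_k,
            linkage_k) <= 0))
    stop("hand material stiffnesses must be > 0")
  structure(list(dorsal_tissue_k = dorsal_tissue_k,
                 palmar_tissue_k = palmar_tissue_k, padding_k = padding_k,
                 strap_k = strap_k, linkage_k = linkage_k,
                 tangential_ratio = tangential_ratio),
            class = "hand_materials")
}

# progressive stiffening tissue law: force (N) vs strain for a lumped layer
.tissue_curve <- function(k_n_mm, thickness, ratio = 1) {
  s0 <- ratio * k_n_mm * thickness * 1e3      # N per unit strain
  stiffness_curve(c(0, 0.15, 0.3, 0.45), s0 * c(1, 2, 8, 50),
                  smoothing_halfwidth = 0.02)
}

.padding_curve <- function(k_n_mm, thickness, ratio = 1) {
  s0 <- ratio * k_n_mm * thickness * 1e3
  stiffness_curve(c(0, 0.3, 0.6), s0 * c(1, 3, 20),
                  smoothing_halfwidth = 0.02)
}

#' Build the two-plate hand-dorsum attachment system
#'
#' Constructs the lumped network: each plate is a rigid ternary body (two
#' contacting end nodes plus a raised apex node whose contact unit has zero
#' properties), the apexes are joined by a compliant exoskeleton linkage and
#' anchored by tension-only straps routed to a palmar pad node whose own
#' contact unit presses against the palm; phalanx-side anchors live in the
#' MCP-posed phalanx ground frame.
#'
#' @param geometry A [hand_geometry()].
#' @param materials A [hand_materials()].
#' @param pretension Strap pretension, N per strap.
#' @param cocontraction_bulge Fractional increase of the palmar tissue rest
#'   thickness emulating muscle-bulge during co-contraction (default 0).
#' @return A [system_model()] with hand metadata in `$meta`.
#' @export
build_hand_system <- function(geometry = hand_geometry(),
                              materials = hand_materials(),
                              pretension = 0, cocontraction_bulge = 0) {
  stopifnot(inherits(geometry, "hand_geometry"),
            inherits(materials, "hand_materials"))
  if (pretension < 0) stop("pretension must be >= 0")
  if (cocontraction_bulge < 0) stop("cocontraction_bulge must be >= 0")
  g <- geometry; mtl <- materials
  td <- g$tissue_thickness_dorsal; tp <- g$padding_thickness
  rest_d <- td + tp
  x_mc <- c(-g$plate_gap - g$metacarpal_plate_length, -g$plate_gap)
  x_ph <- c(g$plate_gap, g$plate_gap + g$phalanx_plate_length)
  if (x_mc[2] >= x_ph[1]) stop("plates overlap the MCP gap")
  y_plate <- rest_d
  y_apex <- y_plate + g$apex_standoff
  mass <- g$node_mass

  sys <- system_model(gravity = FALSE)
  sys <- set_ground_frame(sys, "phalanx",
                          list(type = "rotation_about_point",
                               angle = g$mcp_angle, center = c(0, 0)))
  ph_pt <- function(p) ground_frame_point(sys, "phalanx", p, 0)$p

  # metacarpal plate: nodes 1 (far from MCP), 2 (near MCP), apex 5
  sys <- add_node(sys, 1, c(x_mc[1], y_plate), mass = mass)
  sys <- add_node(sys, 2, c(x_mc[2], y_plate), mass = mass)
  sys <- add_node(sys, 5, c(mean(x_mc), y_apex), mass = mass)
  # phalanx plate: nodes 6 (near MCP), 7 (far), apex 8 (posed at mcp_angle)
  sys <- add_node(sys, 6, ph_pt(c(x_ph[1], y_plate)), mass = mass)
  sys <- add_node(sys, 7, ph_pt(c(x_ph[2], y_plate)), mass = mass)
  sys <- add_node(sys, 8, ph_pt(c(mean(x_ph), y_apex)), mass = mass)
  # palmar pad nodes under each plate midline
  y_palm_anchor <- -0.008
  rest_p0 <- g$tissue_thickness_palmar + tp     # pre-bulge palmar thickness
  sys <- add_node(sys, 11, c(mean(x_mc), y_palm_anchor - rest_p0), mass = mass)
  sys <- add_node(sys, 12, ph_pt(c(mean(x_ph), y_palm_anchor - rest_p0)),
                  mass = mass)

  sys <- add_rigid_body(sys, c(1, 2, 5))
  sys <- add_rigid_body(sys, c(6, 7, 8))

  # elements; damping set critical against the stiffest tangent an element
  # can present, so the bottomed-out contact phase stays non-oscillatory
  damp_for <- function(curve, thickness)
    2 * critical_damping(max(curve$slopes) / thickness, mass)
  make_elem <- function(curve_fn, k, thickness) {
    cn <- curve_fn(k, thickness)
    ct <- curve_fn(k, thickness, mtl$tangential_ratio)
    d <- damp_for(cn, thickness)
    viscoelastic_element(cn, ct, d, d * mtl$tangential_ratio, thickness)
  }
  tissue_d <- make_elem(.tissue_curve, mtl$dorsal_tissue_k, td)
  padding <- make_elem(.padding_curve, mtl$padding_k, tp)
  tissue_p <- make_elem(.tissue_curve, mtl$palmar_tissue_k,
                        g$tissue_thickness_palmar)
  padding_p <- make_elem(.padding_curve, mtl$padding_k, tp)

  # dorsal contact units at plate ends, inert units at the apexes
  sys <- add_phrii_unit(sys, 1, c(x_mc[1], 0), tissue_d, padding,
                        label = "mc_far")
  sys <- add_phrii_unit(sys, 2, c(x_mc[2], 0), tissue_d, padding,
                        label = "mc_near")
  sys <- add_phrii_unit(sys, 5, c(mean(x_mc), 0), inert_element(rest_d),
                        inert_element(1e-3), label = "mc_apex")
  sys <- add_phrii_unit(sys, 6, c(x_ph[1], 0), tissue_d, padding,
                        frame = "phalanx", label = "ph_near")
  sys <- add_phrii_unit(sys, 7, c(x_ph[2], 0), tissue_d, padding,
                        frame = "phalanx", label = "ph_far")
  sys <- add_phrii_unit(sys, 8, c(mean(x_ph), 0), inert_element(rest_d),
                        inert_element(1e-3), label = "ph_apex")
  # palmar pads pressed up against the palm by the straps
  sys <- add_phrii_unit(sys, 11, c(mean(x_mc), y_palm_anchor), tissue_p,
                        padding_p, contact_normal = c(0, -1),
                        label = "palmar_mc")
  sys <- add_phrii_unit(sys, 12, c(mean(x_ph), y_palm_anchor), tissue_p,
                        padding_p, contact_normal = c(0, -1),
                        frame = "phalanx", label = "palmar_ph")

  # straps: each plate carries one strap loop routed over the plate edges,
  # modelled as two tension-only segments from the plate end nodes to the
  # shared palmar pad node (half the loop stiffness and pretension each);
  # edge routing is what lets a strap resist plate rotation
  strap_damp <- critical_damping(mtl$strap_k * 1e3, mass)
  add_strap_segment <- function(sys, node_end, node_pad) {
    i <- match(node_end, sys$nodes$id); j <- match(node_pad, sys$nodes$id)
    rest <- sqrt((sys$nodes$x[i] - sys$nodes$x[j])^2 +
                 (sys$nodes$y[i] - sys$nodes$y[j])^2)
    add_elastic_link(sys, node_end, node_pad,
                     stiffness_curve = stiffness_curve(0, (mtl$strap_k / 2) * 1e3 * rest,
                                                       smoothing_halfwidth = 0),
                     rest_length = rest, pretension = pretension / 2,
                     tension_only = TRUE, damping = strap_damp)
  }
  sys <- add_strap_segment(sys, 1, 11)
  sys <- add_strap_segment(sys, 2, 11)
  sys <- add_strap_segment(sys, 6, 12)
  sys <- add_strap_segment(sys, 7, 12)
  # exoskeleton linkage compliance between the apexes
  link_len <- sqrt(sum((ph_pt(c(mean(x_ph), y_apex)) -
                        c(mean(x_mc), y_apex))^2))
  sys <- add_elastic_link(sys, 5, 8,
                          stiffness_curve = stiffness_curve(0, mtl$linkage_k * 1e3 * link_len,
                                                            smoothing_halfwidth = 0),
                          rest_length = link_len,
                          damping = critical_damping(mtl$linkage_k * 1e3, mass))

  sys$meta <- list(
    geometry = g, materials = mtl, pretension = pretension,
    cocontraction_bulge = cocontraction_bulge,
    metacarpal_body = c(1, 2, 5), phalanx_body = c(6, 7, 8),
    plate_nodes = list(metacarpal = c(1, 2), phalanx = c(6, 7)),
    dorsal_units = c("mc_far", "mc_near", "ph_near", "ph_far"),
    near_mcp_units = c(metacarpal = "mc_near", phalanx = "ph_near"),
    tributary = c(mc_far = g$metacarpal_plate_length / 2,
                  mc_near = g$metacarpal_plate_length / 2,
                  ph_near = g$phalanx_plate_length / 2,
                  ph_far = g$phalanx_plate_length / 2),
    strap_loops = list(metacarpal = c(1L, 2L), phalanx = c(3L, 4L)),
    strap_links = 1:4, linkage_link = 5L,
    palmar_units = c("palmar_mc", "palmar_ph"))
  if (pretension > 0) sys <- set_strap_pretension(sys, pretension)
  if (cocontraction_bulge > 0)
    sys <- apply_cocontraction_bulge(sys, cocontraction_bulge)
  sys
}

#' Thicken the palmar cross-section to emulate muscle co-contraction
#'
#' Applied after strap pretensioning (contraction happens with the device
#' already donned): the palmar tissue rest thickness is scaled by
#' `1 + bulge` and its stiffness by `1 + stiffening * bulge` (active muscle
#' is both thicker and much stiffer than relaxed muscle).  The thickened,
#' stiffened cross-section drives the palmar pad outward, stretches the
#' straps and raises interface pressure -- strongly so for stiff straps,
#' which cannot absorb the girth change.
#'
#' @param system A hand system from [build_hand_system()].
#' @param bulge Fractional thickness increase, `>= 0`.
#' @param stiffening Palmar stiffness multiplier per unit bulge (default 10:
#'   a 10 % bulge doubles the palmar stiffness).
#' @return The updated system.
#' @export
apply_cocontraction_bulge <- function(system, bulge, stiffening = 10) {
  if (bulge < 0) stop("bulge must be >= 0")
  m <- system$meta
  if (is.null(m)) stop("system carries no hand metadata")
  if (bulge == 0) return(system)
  labels <- vapply(system$phrii_units, `[[`, character(1), "label")
  for (lab in m$palmar_units) {
    k <- match(lab, labels)
    u <- system$phrii_units[[k]]
    tis <- u$tissue
    t_new <- tis$rest_thickness * (1 + bulge)
    sfac <- 1 + stiffening * bulge
    scale_curve <- function(cv)
      stiffness_curve(cv$breakpoints, cv$slopes * sfac,
                      smoothing_halfwidth = cv$smoothing_halfwidth)
    tis_new <- viscoelastic_element(scale_curve(tis$elastic_normal),
                                    scale_curve(tis$elastic_tangential),
                                    tis$damping_normal, tis$damping_tangential,
                                    t_new)
    u$tissue <- tis_new
    u$rest_thickness <- t_new + u$padding$rest_thickness
    u$normal_curve <- series_displacement_curve(
      tis_new$elastic_normal, t_new,
      u$padding$elastic_normal, u$padding$rest_thickness)
    u$tangential_curve <- series_displacement_curve(
      tis_new$elastic_tangential, t_new,
      u$padding$elastic_tangential, u$padding$rest_thickness)
    system$phrii_units[[k]] <- u
  }
  system$meta$cocontraction_bulge <- bulge
  system
}

#' Set and calibrate the strap pretension of a hand system
#'
#' Mirrors the experimental pre-tensioning protocol: straps are tightened to
#' the target tension with the tissue already settled under the preload.
#' Calibration settles the unloaded system with each strap acting as a
#' constant-force tensioner at the target tension (the buckle is free while
#' tightening), then locks every segment's rest length at the settled
#' geometry and adopts that state as the new construction / reference
#' state.  The result is an exact equilibrium in which each strap carries
#' its nominal pretension.
#'
#' @param system A [system_model()] with tension-only strap links.
#' @param pretension New pretension, N per strap loop, `>= 0`.
#' @param settle Run the tension calibration (default TRUE when the system
#'   carries hand metadata).
#' @param ... Passed to [steady_state()].
#' @return The updated system, at its pretensioned reference state.
#' @export
set_strap_pretension <- function(system, pretension, settle = TRUE, ...) {
  if (pretension < 0) stop("pretension must be >= 0")
  # straps are stored as two edge-routed segments per loop
  strap_ix <- which(vapply(system$elastic_links, `[[`, logical(1),
                           "tension_only"))
  k_abs <- vapply(strap_ix, function(i) {
    l <- system$elastic_links[[i]]
    l$stiffness_curve$slopes[1] / l$rest_length       # N/m equivalent
  }, numeric(1))
  for (i in strap_ix)
    system$elastic_links[[i]]$pretension <- pretension / 2
  if (!is.null(system$meta)) system$meta$pretension <- pretension
  if (!settle || pretension == 0 || is.null(system$meta)) return(system)
  # 1. settle with force-controlled straps (negligible stiffness)
  relaxed <- system
  for (i in strap_ix)
    relaxed$elastic_links[[i]]$stiffness_curve <-
      stiffness_curve(0, 1e-6, smoothing_halfwidth = 0)
  ss <- steady_state(relaxed, NULL, rtol = 1e-4, atol = 1e-7, ...)
  # 2. adopt the settled state and lock the buckles there
  n <- nrow(system$nodes)
  q <- ss$state$q
  system$nodes$x <- q[seq(1, 2 * n, by = 2)]
  system$nodes$y <- q[seq(2, 2 * n, by = 2)]
  system$nodes$vx <- 0
  system$nodes$vy <- 0
  for (s in seq_along(strap_ix)) {
    i <- strap_ix[s]
    l <- system$elastic_links[[i]]
    ia <- match(l$node_a, system$nodes$id)
    ib <- match(l$node_b, system$nodes$id)
    len <- sqrt((system$nodes$x[ia] - system$nodes$x[ib])^2 +
                (system$nodes$y[ia] - system$nodes$y[ib])^2)
    system$elastic_links[[i]]$rest_length <- len
    system$elastic_links[[i]]$stiffness_curve <-
      stiffness_curve(0, k_abs[s] * len, smoothing_halfwidth = 0)
  }
  system
}

#' Isometric MCP moment load on the hand system
#'
#' The commanded moment about the MCP (positive = extension) is applied as
#' the moment load transmitted across each attachment: an equal-sense couple
#' on the phalanx plate and on the metacarpal plate.  The sign convention is
#' anchored to the observed phenomenology: under extension the phalanx
#' plate's near-MCP edge unloads (and eventually lifts off) while the
#' metacarpal plate loads up nearest the joint.
#'
#' @param system A hand system from [build_hand_system()].
#' @param moment Applied MCP moment, N m (positive = extension).
#' @param ramp_time Ramp duration, s.
#' @return A [load_case()].
#' @export
hand_moment_load <- function(system, moment, ramp_time = 0.05) {
  m <- system$meta
  if (is.null(m)) stop("system carries no hand metadata")
  load_case(body_moments = list(
    list(nodes = m$plate_nodes$phalanx, moment = ramp_hold(-moment, ramp_time)),
    list(nodes = m$plate_nodes$metacarpal, moment = ramp_hold(-moment, ramp_time))))
}

# signed rotation (rad) of a plate from its construction orientation
.plate_angle <- function(system, state, nodes) {
  i <- match(nodes, system$nodes$id)
  p1 <- state$q[c(2 * i[1] - 1, 2 * i[1])]
  p2 <- state$q[c(2 * i[2] - 1, 2 * i[2])]
  v_now <- p2 - p1
  v_ref <- c(system$nodes$x[i[2]] - system$nodes$x[i[1]],
             system$nodes$y[i[2]] - system$nodes$y[i[1]])
  atan2(v_now[2], v_now[1]) - atan2(v_ref[2], v_ref[1])
}

.plate_centroid_disp <- function(system, state, nodes) {
  i <- match(nodes, system$nodes$id)
  dx <- mean(state$q[2 * i - 1] - system$nodes$x[i])
  dy <- mean(state$q[2 * i] - system$nodes$y[i])
  sqrt(dx^2 + dy^2)
}

# summarise one settled hand state into a study row
.hand_summary <- function(system, ss) {
  m <- system$meta
  labels <- vapply(system$phrii_units, `[[`, character(1), "label")
  di <- match(m$dorsal_units, labels)
  pressures <- ss$normal_force[di] / m$tributary[m$dorsal_units]
  names(pressures) <- m$dorsal_units
  lift <- detect_liftoff_pattern(ss, system)
  data.frame(
    angle_deg = .plate_angle(system, ss$state, m$plate_nodes$phalanx) * 180 / pi,
    rel_disp_mm = .plate_centroid_disp(system, ss$state, m$plate_nodes$phalanx) * 1e3,
    peak_pressure_n_m = max(pressures),
    p_mc_far = pressures[["mc_far"]], p_mc_near = pressures[["mc_near"]],
    p_ph_near = pressures[["ph_near"]], p_ph_far = pressures[["ph_far"]],
    liftoff_end = lift$which_end_lifted, liftoff_gap_mm = lift$gap * 1e3,
    max_strap_tension_n = max(vapply(m$strap_loops, function(ix)
      sum(ss$link_tension[ix]), numeric(1))))
}

#' Run the isometric moment / pretension study
#'
#' For each (moment, pretension) grid point the system is settled to steady
#' state and the angular displacement of the phalanx attachment, the
#' relative displacement against the skeleton, per-unit dorsal contact
#' pressures (line pressure, N/m of plate length) and the lift-off pattern
#' are recorded.
#'
#' @param system A hand system from [build_hand_system()].
#' @param moment_grid Applied MCP moments, N m (positive = extension).
#' @param pretension_grid Strap pretensions, N.
#' @param ... Passed to [steady_state()].
#' @return A data frame with one row per grid point.
#' @export
run_isometric_moment_study <- function(system, moment_grid,
                                       pretension_grid, ...) {
  if (!length(moment_grid) || !length(pretension_grid))
    stop("moment and pretension grids must be non-empty")
  rows <- list()
  for (P in pretension_grid) {
    sysP <- set_strap_pretension(system, P)
    for (M in moment_grid) {
      ss <- tryCatch(
        steady_state(sysP, hand_moment_load(sysP, M), ...),
        error = function(e) stop("steady state failed at moment = ", M,
                                 " N m, pretension = ", P, " N: ",
                                 conditionMessage(e)))
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(moment_nm = M, pretension_n = P),
              .hand_summary(sysP, ss))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify the phalanx-plate lift-off pattern of a settled state
#'
#' @param ss A [steady_state()] result for a hand system.
#' @param system The hand system it came from.
#' @return List with `which_end_lifted` (`"near_mcp"`, `"far_mcp"` or
#'   `"none"`, judged on the phalanx plate) and the open `gap` in m.
#' @export
detect_liftoff_pattern <- function(ss, system) {
  labels <- vapply(system$phrii_units, `[[`, character(1), "label")
  near <- match("ph_near", labels)
  far <- match("ph_far", labels)
  if (is.na(near) || is.na(far)) stop("not a hand system (missing phalanx units)")
  lifted_near <- !ss$in_contact[near] && ss$gap[near] > 0
  lifted_far <- !ss$in_contact[far] && ss$gap[far] > 0
  if (lifted_near && (!lifted_far || ss$gap[near] >= ss$gap[far]))
    list(which_end_lifted = "near_mcp", gap = max(0, ss$gap[near]))
  else if (lifted_far)
    list(which_end_lifted = "far_mcp", gap = max(0, ss$gap[far]))
  else list(which_end_lifted = "none", gap = 0)
}

#' Strap-stiffness sweep with optional co-contraction bulge
#'
#' Rebuilds the hand system for each strap stiffness and settles it under a
#' fixed extension moment.  With no bulge, stiffer straps are never worse on
#' either metric; a palmar bulge penalises very stiff straps (the thickened
#' cross-section drives strap tension and hence contact pressure up), which
#' is what creates an interior peak-pressure optimum at finite stiffness.
#'
#' @param stiffness_grid Strap stiffnesses, N/mm.
#' @param cocontraction_bulge Fractional palmar thickening.
#' @param moment Applied extension moment, N m.
#' @param pretension Strap pretension, N.
#' @param geometry,materials Scenario definition; `materials$strap_k` is
#'   overridden by the grid.
#' @param ... Passed to [steady_state()].
#' @return Data frame `(strap_k_n_mm, peak_pressure_n_m, rel_disp_mm,
#'   angle_deg, max_strap_tension_n)`.
#' @export
strap_stiffness_study <- function(stiffness_grid, cocontraction_bulge = 0,
                                  moment = 0.3, pretension = 2,
                                  geometry = hand_geometry(),
                                  materials = hand_materials(), ...) {
  if (cocontraction_bulge < 0) stop("bulge must be >= 0")
  rows <- list()
  for (k in stiffness_grid) {
    mtl <- materials
    mtl$strap_k <- k
    sys <- build_hand_system(geometry, mtl, pretension = pretension,
                             cocontraction_bulge = cocontraction_bulge)
    ss <- steady_state(sys, hand_moment_load(sys, moment), ...)
    s <- .hand_summary(sys, ss)
    rows[[length(rows) + 1L]] <- data.frame(
      strap_k_n_mm = k, peak_pressure_n_m = s$peak_pressure_n_m,
      rel_disp_mm = s$rel_disp_mm, angle_deg = s$angle_deg,
      max_strap_tension_n = s$max_strap_tension_n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
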