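#' Create an empty lumped-parameter interface system
#'
#' A `system_model` holds point-mass nodes, inelastic (rigid) distance
#' constraints, elastic links (straps, linkage compliance), contact units
#' (series tissue + padding elements against a reference ground) and named
#' ground frames.  The human skeleton is the reference ground: it is never
#' a simulated body, only a (possibly moving) frame that contact anchors and
#' strap anchors are expressed in.
#'
#' @param gravity Logical; include gravity (`-y`) on every node.  Off by
#'   default: the interface studies are quasi-static and gram-scale node
#'   masses make weight negligible against strap and contact forces.
#' @return An object of class `system_model`.
#' @export
system_model <- function(gravity = FALSE) {
  structure(
    list(
      schema_version = 1L,
      nodes = data.frame(id = integer(), x = numeric(), y = numeric(),
                         vx = numeric(), vy = numeric(), mass = numeric()),
      inelastic = data.frame(node_a = integer(), node_b = integer(),
                             target = numeric()),
      ground_constraints = data.frame(node = integer(), ax = numeric(),
                                      ay = numeric(), target = numeric(),
                                      frame = character()),
      bodies = list(),
      elastic_links = list(),
      phrii_units = list(),
      ground_frames = list(world = list(type = "identity")),
      gravity = isTRUE(gravity)
    ),
    class = "system_model"
  )
}

#' @export
print.system_model <- function(x, ...) {
  cat("<system_model> ", nrow(x$nodes), " nodes, ",
      nrow(x$inelastic), " inelastic constraints, ",
      length(x$elastic_links), " elastic links, ",
      length(x$phrii_units), " contact units\n", sep = "")
  invisible(x)
}

.check_node_exists <- function(system, id, what = "node") {
  missing <- setdiff(id, system$nodes$id)
  if (length(missing))
    stop(what, " references unknown node id(s): ",
         paste(missing, collapse = ", "))
}

#' Add a point-mass node
#'
#' @param system A [system_model()].
#' @param id Integer id, unique within the system.
#' @param position Length-2 numeric, m.
#' @param velocity Length-2 numeric, m/s.
#' @param mass Mass in kg, `> 0`.  Node masses are not reported in the
#'   interface literature; the 5 g default is the order of magnitude of a
#'   small exoskeleton link segment.  Steady-state interface forces are
#'   mass-independent.
#' @return The updated system.
#' @export
add_node <- function(system, id, position, velocity = c(0, 0), mass = 0.005) {
  stopifnot(inherits(system, "system_model"), length(position) == 2)
  id <- as.integer(id)
  if (id %in% system$nodes$id) stop("node id ", id, " already exists")
  if (!is.finite(mass) || mass <= 0) stop("mass must be > 0")
  system$nodes <- rbind(system$nodes,
                        data.frame(id = id, x = position[1], y = position[2],
                                   vx = velocity[1], vy = velocity[2],
                                   mass = mass))
  system
}

.current_distance <- function(system, a, b) {
  pa <- unlist(system$nodes[system$nodes$id == a, c("x", "y")])
  pb <- unlist(system$nodes[system$nodes$id == b, c("x", "y")])
  sqrt(sum((pa - pb)^2))
}

#' Add an inelastic (rigid distance) constraint between two nodes
#'
#' @param system A [system_model()].
#' @param node_a,node_b Distinct node ids.
#' @param target Constrained distance, m; default the current distance.
#' @return The updated system.  Duplicate pairs are ignored (idempotent).
#' @export
add_inelastic_constraint <- function(system, node_a, node_b, target = NULL) {
  stopifnot(inherits(system, "system_model"))
  if (node_a == node_b) stop("constraint endpoints must be distinct nodes")
  .check_node_exists(system, c(node_a, node_b), "inelastic constraint")
  key <- sort(c(node_a, node_b))
  exists <- any(pmin(system$inelastic$node_a, system$inelastic$node_b) == key[1] &
                pmax(system$inelastic$node_a, system$inelastic$node_b) == key[2])
  if (exists) return(system)
  if (is.null(target)) target <- .current_distance(system, node_a, node_b)
  if (target <= 0) stop("target_distance must be > 0")
  system$inelastic <- rbind(system$inelastic,
                            data.frame(node_a = as.integer(node_a),
                                       node_b = as.integer(node_b),
                                       target = target))
  system
}

#' Pin a node at fixed distance from a ground anchor point
#'
#' @param system A [system_model()].
#' @param node Node id.
#' @param anchor Length-2 anchor point in the given ground frame, m.
#' @param target Distance, m; default current.
#' @param frame Ground frame name (default `"world"`).
#' @return Updated system.
#' @export
add_ground_constraint <- function(system, node, anchor, target = NULL,
                                  frame = "world") {
  stopifnot(inherits(system, "system_model"), length(anchor) == 2)
  .check_node_exists(system, node, "ground constraint")
  if (!frame %in% names(system$ground_frames))
    stop("unknown ground frame '", frame, "'")
  if (is.null(target)) {
    p <- unlist(system$nodes[system$nodes$id == node, c("x", "y")])
    aw <- ground_frame_point(system, frame, anchor, 0)$p
    target <- sqrt(sum((p - aw)^2))
  }
  if (target <= 0) stop("target distance must be > 0")
  system$ground_constraints <- rbind(
    system$ground_constraints,
    data.frame(node = as.integer(node), ax = anchor[1], ay = anchor[2],
               target = target, frame = frame))
  system
}

#' Declare three nodes a rigid ternary body
#'
#' Adds the three pairwise inelastic constraints at the current distances,
#' so the triple moves as a rigid body under the constrained dynamics.
#' Re-adding the same triple is a no-op; collinear triples are rejected
#' because they leave the out-of-line direction unconstrained.
#'
#' @param system A [system_model()].
#' @param node_ids Three distinct existing node ids.
#' @return The updated system, with the triple recorded in `system$bodies`.
#' @export
add_rigid_body <- function(system, node_ids) {
  stopifnot(inherits(system, "system_model"))
  node_ids <- as.integer(node_ids)
  if (length(node_ids) != 3 || anyDuplicated(node_ids))
    stop("a rigid ternary body needs exactly three distinct nodes")
  .check_node_exists(system, node_ids, "rigid body")
  P <- as.matrix(system$nodes[match(node_ids, system$nodes$id), c("x", "y")])
  area2 <- abs((P[2, 1] - P[1, 1]) * (P[3, 2] - P[1, 2]) -
               (P[3, 1] - P[1, 1]) * (P[2, 2] - P[1, 2]))
  scale <- max(dist(P))
  if (area2 < 1e-12 * scale^2)
    stop("rigid body nodes are collinear; orientation would be indeterminate")
  for (pair in list(node_ids[c(1, 2)], node_ids[c(1, 3)], node_ids[c(2, 3)]))
    system <- add_inelastic_constraint(system, pair[1], pair[2])
  if (!any(vapply(system$bodies,
                  function(b) setequal(b, node_ids), logical(1))))
    system$bodies <- c(system$bodies, list(node_ids))
  system
}

#' Add an elastic link (strap or linkage compliance)
#'
#' Connects a node either to another node or to a ground anchor through a
#' nonlinear spring with optional pretension.  `tension_only` links (straps)
#' carry no compressive force.
#'
#' @param system A [system_model()].
#' @param node_a Node id at one end.
#' @param node_b Node id at the other end, or `NULL` for a ground anchor.
#' @param anchor Length-2 ground anchor (m, in `frame`) when `node_b` is NULL.
#' @param stiffness_curve Force (N) vs. strain = extension / rest_length.
#' @param rest_length Unstretched length, m; default the current separation.
#' @param pretension Tensile preload at the construction configuration, N.
#' @param tension_only Clamp compressive force to zero (straps).
#' @param damping Axial viscous coefficient, N s/m.
#' @param strain_offset Additional imposed strain (used to emulate, e.g.,
#'   muscle-bulge thickening of the strapped cross-section).
#' @param frame Ground frame for `anchor`.
#' @return The updated system.
#' @export
add_elastic_link <- function(system, node_a, node_b = NULL, anchor = NULL,
                             stiffness_curve, rest_length = NULL,
                             pretension = 0, tension_only = FALSE,
                             damping = 0, strain_offset = 0,
                             frame = "world") {
  stopifnot(inherits(system, "system_model"),
            inherits(stiffness_curve, "stiffness_curve"))
  .check_node_exists(system, node_a, "elastic link")
  if (is.null(node_b) && is.null(anchor))
    stop("elastic link needs node_b or a ground anchor")
  if (!is.null(node_b)) .check_node_exists(system, node_b, "elastic link")
  if (pretension < 0) stop("pretension must be >= 0")
  if (is.null(rest_length)) {
    pa <- unlist(system$nodes[system$nodes$id == node_a, c("x", "y")])
    pb <- if (!is.null(node_b))
      unlist(system$nodes[system$nodes$id == node_b, c("x", "y")])
    else ground_frame_point(system, frame, anchor, 0)$p
    rest_length <- sqrt(sum((pa - pb)^2))
  }
  if (rest_length <= 0) stop("rest_length must be > 0")
  link <- list(node_a = as.integer(node_a),
               node_b = if (is.null(node_b)) NA_integer_ else as.integer(node_b),
               anchor = if (is.null(anchor)) c(NA_real_, NA_real_) else anchor,
               stiffness_curve = stiffness_curve,
               rest_length = rest_length, pretension = pretension,
               tension_only = isTRUE(tension_only), damping = damping,
               strain_offset = strain_offset, frame = frame)
  system$elastic_links <- c(system$elastic_links, list(link))
  system
}

#' Add a contact (PHRII) unit
#'
#' One contact point between the device network and the body: a tissue
#' element and a padding element in series, normal and tangential directions
#' independent, transmitting force only while in compressive contact.
#'
#' @param system A [system_model()].
#' @param node Node id of the device-side mass.
#' @param ground_anchor Length-2 skin-surface anchor in `frame` coordinates, m.
#' @param tissue,padding [viscoelastic_element()]s (use [inert_element()] for
#'   non-contacting network points).
#' @param contact_normal Unit 2-vector from ground toward the node.
#' @param tangential_cap Optional absolute bound on tangential force, N
#'   (`Inf` = pure compliance-limited slip, the default).
#' @param frame Ground frame name.
#' @param label Optional label used in study outputs.
#' @return The updated system.
#' @export
add_phrii_unit <- function(system, node, ground_anchor, tissue, padding,
                           contact_normal = c(0, 1), tangential_cap = Inf,
                           frame = "world", label = NULL) {
  stopifnot(inherits(system, "system_model"),
            inherits(tissue, "viscoelastic_element"),
            inherits(padding, "viscoelastic_element"),
            length(ground_anchor) == 2, length(contact_normal) == 2)
  .check_node_exists(system, node, "contact unit")
  if (!frame %in% names(system$ground_frames))
    stop("unknown ground frame '", frame, "'")
  nrm <- contact_normal / sqrt(sum(contact_normal^2))
  inert <- all(tissue$elastic_normal$slopes == 0) ||
           all(padding$elastic_normal$slopes == 0)
  unit <- list(node = as.integer(node), ground_anchor = ground_anchor,
               tissue = tissue, padding = padding, contact_normal = nrm,
               tangential_cap = tangential_cap, frame = frame,
               inert = inert,
               label = if (is.null(label)) paste0("unit_", length(system$phrii_units) + 1L)
                       else label)
  # precompute series displacement-domain curves and series damping
  unit$rest_thickness <- tissue$rest_thickness + padding$rest_thickness
  unit$normal_curve <- series_displacement_curve(
    tissue$elastic_normal, tissue$rest_thickness,
    padding$elastic_normal, padding$rest_thickness)
  unit$tangential_curve <- series_displacement_curve(
    tissue$elastic_tangential, tissue$rest_thickness,
    padding$elastic_tangential, padding$rest_thickness)
  unit$damping_normal <- .series_damping(tissue$damping_normal,
                                         padding$damping_normal)
  unit$damping_tangential <- .series_damping(tissue$damping_tangential,
                                             padding$damping_tangential)
  # natural tangential offset of the node over its anchor at construction
  p <- unlist(system$nodes[system$nodes$id == node, c("x", "y")])
  aw <- ground_frame_point(system, frame, ground_anchor, 0)$p
  tang <- c(-nrm[2], nrm[1])
  unit$tangential_offset <- sum((p - aw) * tang)
  system$phrii_units <- c(system$phrii_units, list(unit))
  system
}

# series coupling of two viscous coefficients; a zero member gives zero
.series_damping <- function(r1, r2) {
  if (r1 <= 0 || r2 <= 0) return(0)
  r1 * r2 / (r1 + r2)
}

#' Register a named ground frame
#'
#' Ground frames carry the rigid transform of a piece of the human reference
#' skeleton (for instance a phalanx posed at a joint angle) relative to the
#' world frame.  Supported specifications: `list(type = "identity")` and
#' `list(type = "rotation_about_point", angle = <rad>, center = c(x, y))`.
#'
#' @param system A [system_model()].
#' @param name Frame name.
#' @param spec Frame specification list.
#' @return The updated system.
#' @export
set_ground_frame <- function(system, name, spec) {
  stopifnot(inherits(system, "system_model"), is.list(spec), !is.null(spec$type))
  if (!spec$type %in% c("identity", "rotation_about_point"))
    stop("unsupported ground frame type '", spec$type, "'")
  system$ground_frames[[name]] <- spec
  system
}

#' Map a ground-frame point into the world frame
#'
#' @param system A [system_model()].
#' @param frame Frame name.
#' @param point Length-2 point in frame coordinates.
#' @param t Time (reserved for time-varying frames; current frame types are
#'   static so velocity and acceleration are zero).
#' @return List with world position `p`, velocity `v` and acceleration `a`.
#' @export
ground_frame_point <- function(system, frame, point, t = 0) {
  spec <- system$ground_frames[[frame]]
  if (is.null(spec)) stop("unknown ground frame '", frame, "'")
  if (spec$type == "identity")
    return(list(p = as.numeric(point), v = c(0, 0), a = c(0, 0)))
  th <- spec$angle
  ctr <- as.numeric(spec$center)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  list(p = as.numeric(ctr + R %*% (as.numeric(point) - ctr)),
       v = c(0, 0), a = c(0, 0))
}

#' Validate a system model
#'
#' Checks referential integrity (constraints, links and contact units refer
#' to existing nodes and frames) and basic invariants.  Returns a character
#' vector of violations, empty when valid; `stop_on_error = TRUE` raises
#' instead.
#'
#' @param system A [system_model()].
#' @param stop_on_error Raise on first report of problems.
#' @return Character vector of violation messages (invisibly when empty).
#' @export
validate_system <- function(system, stop_on_error = FALSE) {
  problems <- character()
  if (anyDuplicated(system$nodes$id))
    problems <- c(problems, "duplicate node ids")
  if (any(system$nodes$mass <= 0))
    problems <- c(problems, "node masses must be > 0")
  known <- system$nodes$id
  for (i in seq_len(nrow(system$inelastic))) {
    row <- system$inelastic[i, ]
    bad <- setdiff(c(row$node_a, row$node_b), known)
    if (length(bad))
      problems <- c(problems, paste0("inelastic constraint ", i,
                                     " references missing node ", bad))
    if (row$target <= 0)
      problems <- c(problems, paste0("inelastic constraint ", i,
                                     " has non-positive target distance"))
  }
  for (i in seq_along(system$elastic_links)) {
    l <- system$elastic_links[[i]]
    ids <- c(l$node_a, if (!is.na(l$node_b)) l$node_b)
    bad <- setdiff(ids, known)
    if (length(bad))
      problems <- c(problems, paste0("elastic link ", i,
                                     " references missing node ", bad))
    if (l$rest_length <= 0)
      problems <- c(problems, paste0("elastic link ", i,
                                     " has non-positive rest_length"))
  }
  for (i in seq_along(system$phrii_units)) {
    u <- system$phrii_units[[i]]
    if (!u$node %in% known)
      problems <- c(problems, paste0("contact unit ", i,
                                     " references missing node ", u$node))
    if (!u$frame %in% names(system$ground_frames))
      problems <- c(problems, paste0("contact unit ", i,
                                     " references missing frame ", u$frame))
  }
  if (length(problems) && stop_on_error)
    stop(paste(problems, collapse = "\n"))
  if (length(problems)) problems else invisible(character())
}
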