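#' Write a system model to a YAML file
#'
#' The on-disk schema is versioned and stores the construction inputs
#' (nodes, constraints, link and contact-unit parameters); reading replays
#' the construction so derived quantities (series curves, offsets) are
#' rebuilt identically.
#'
#' @param system A [system_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
serialize_system <- function(system, path) {
  stopifnot(inherits(system, "system_model"))
  curve2list <- function(cv) list(breakpoints = cv$breakpoints,
                                  slopes = cv$slopes,
                                  smoothing_halfwidth = cv$smoothing_halfwidth)
  elem2list <- function(el) list(
    elastic_normal = curve2list(el$elastic_normal),
    elastic_tangential = curve2list(el$elastic_tangential),
    damping_normal = el$damping_normal,
    damping_tangential = el$damping_tangential,
    rest_thickness = el$rest_thickness)
  doc <- list(
    schema_version = system$schema_version,
    gravity = system$gravity,
    ground_frames = system$ground_frames,
    nodes = lapply(seq_len(nrow(system$nodes)), function(i)
      as.list(system$nodes[i, ])),
    inelastic = lapply(seq_len(nrow(system$inelastic)), function(i)
      as.list(system$inelastic[i, ])),
    ground_constraints = lapply(seq_len(nrow(system$ground_constraints)),
                                function(i) as.list(system$ground_constraints[i, ])),
    bodies = system$bodies,
    elastic_links = lapply(system$elastic_links, function(l) {
      l$stiffness_curve <- curve2list(l$stiffness_curve)
      l
    }),
    phrii_units = lapply(system$phrii_units, function(u) list(
      node = u$node, ground_anchor = u$ground_anchor,
      tissue = elem2list(u$tissue), padding = elem2list(u$padding),
      contact_normal = u$contact_normal, tangential_cap = u$tangential_cap,
      frame = u$frame, label = u$label))
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Read a system model from a YAML file
#'
#' @param path File written by [serialize_system()].
#' @return A [system_model()].  Referential errors (e.g. a constraint naming
#'   a missing node) are raised with the offending entry identified.
#' @export
deserialize_system <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$schema_version) || doc$schema_version != 1L)
    stop("unsupported or missing schema_version (expected 1)")
  list2curve <- function(x) stiffness_curve(x$breakpoints, x$slopes,
                                            x$smoothing_halfwidth)
  list2elem <- function(x) viscoelastic_element(
    list2curve(x$elastic_normal), list2curve(x$elastic_tangential),
    x$damping_normal, x$damping_tangential, x$rest_thickness)
  sys <- system_model(gravity = isTRUE(doc$gravity))
  for (nm in names(doc$ground_frames))
    sys <- set_ground_frame(sys, nm, doc$ground_frames[[nm]])
  for (nd in doc$nodes)
    sys <- add_node(sys, nd$id, c(nd$x, nd$y), c(nd$vx, nd$vy), nd$mass)
  for (i in seq_along(doc$inelastic)) {
    cn <- doc$inelastic[[i]]
    if (!all(c(cn$node_a, cn$node_b) %in% sys$nodes$id))
      stop("inelastic constraint ", i, " (", cn$node_a, "-", cn$node_b,
           ") references a node missing from the file")
    sys <- add_inelastic_constraint(sys, cn$node_a, cn$node_b, cn$target)
  }
  for (gc in doc$ground_constraints)
    sys <- add_ground_constraint(sys, gc$node, c(gc$ax, gc$ay), gc$target,
                                 gc$frame)
  for (b in doc$bodies) {
    sys <- add_rigid_body(sys, unlist(b))
  }
  for (i in seq_along(doc$elastic_links)) {
    l <- doc$elastic_links[[i]]
    if (!is.null(l$node_b) && !is.na(l$node_b) && !l$node_b %in% sys$nodes$id)
      stop("elastic link ", i, " references missing node ", l$node_b)
    sys <- add_elastic_link(
      sys, l$node_a,
      node_b = if (is.null(l$node_b) || is.na(l$node_b)) NULL else l$node_b,
      anchor = if (all(is.na(unlist(l$anchor)))) NULL else unlist(l$anchor),
      stiffness_curve = list2curve(l$stiffness_curve),
      rest_length = l$rest_length, pretension = l$pretension,
      tension_only = isTRUE(l$tension_only), damping = l$damping,
      strain_offset = l$strain_offset, frame = l$frame)
  }
  for (u in doc$phrii_units)
    sys <- add_phrii_unit(sys, u$node, unlist(u$ground_anchor),
                          list2elem(u$tissue), list2elem(u$padding),
                          contact_normal = unlist(u$contact_normal),
                          tangential_cap = if (is.null(u$tangential_cap) ||
                                               !is.finite(u$tangential_cap)) Inf
                                           else u$tangential_cap,
                          frame = u$frame, label = u$label)
  err <- validate_system(sys)
  if (length(err)) stop(paste(err, collapse = "\n"))
  sys
}
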