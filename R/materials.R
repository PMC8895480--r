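#' Viscoelastic element (one layer of a contact unit)
#'
#' One tissue or padding layer: elastic stiffness curves for the normal and
#' tangential directions plus viscous coefficients and a rest thickness.
#' Normal and tangential behaviour are orthogonal and treated independently.
#'
#' @param elastic_normal,elastic_tangential [stiffness_curve()]s giving force
#'   (N) versus strain for compression and for skin glide / padding shear.
#' @param damping_normal,damping_tangential Viscous coefficients, N s/m,
#'   `>= 0`.  Use [critical_damping()] for a sensible transient default.
#' @param rest_thickness Unloaded layer thickness, m, `> 0`.
#' @return An object of class `viscoelastic_element`.
#' @export
viscoelastic_element <- function(elastic_normal, elastic_tangential,
                                 damping_normal = 0, damping_tangential = 0,
                                 rest_thickness) {
  stopifnot(inherits(elastic_normal, "stiffness_curve"),
            inherits(elastic_tangential, "stiffness_curve"))
  if (damping_normal < 0 || damping_tangential < 0)
    stop("damping coefficients must be >= 0")
  if (!is.finite(rest_thickness) || rest_thickness <= 0)
    stop("rest_thickness must be > 0")
  structure(
    list(elastic_normal = elastic_normal,
         elastic_tangential = elastic_tangential,
         damping_normal = damping_normal,
         damping_tangential = damping_tangential,
         rest_thickness = rest_thickness),
    class = "viscoelastic_element"
  )
}

#' Inert viscoelastic element
#'
#' All stiffness and damping set to zero: a placeholder contact unit that
#' transmits no force (used for network nodes that are not in contact with
#' the body).
#'
#' @param rest_thickness Nominal thickness, m (geometry only).
#' @return A `viscoelastic_element` with zero properties.
#' @export
inert_element <- function(rest_thickness = 1e-3) {
  z <- stiffness_curve(0, 0, smoothing_halfwidth = 0)
  viscoelastic_element(z, z, 0, 0, rest_thickness)
}

#' Default material parameter table
#'
#' Ships the tensile/tangential skin law used throughout (initial modulus
#' 0.1 MPa up to strain 0.4, then a single stiff segment of 18.8 MPa
#' representing collagen engagement) together with two-segment compressive
#' placeholder laws for skin and subcutaneous tissue and a generic foam
#' padding.  The compressive entries are editable placeholders: published
#' compressive stress-strain data for the hand dorsum are not tabulated
#' digitally, so these defaults encode only the qualitative shape (soft toe
#' region, sharp stiffening) and should be replaced with measured values
#' when available.
#'
#' @return A data.frame with columns `material`, `direction`,
#'   `breakpoint_strain`, `slope`, `units`.
#' @export
default_material_table <- function() {
  path <- system.file("extdata", "materials_default.csv", package = "phrisim")
  if (nzchar(path)) return(utils::read.csv(path, stringsAsFactors = FALSE))
  # fallback when running from a source tree
  utils::read.csv(text =
"material,direction,breakpoint_strain,slope,units
skin,tangential,0,0.1,MPa
skin,tangential,0.4,18.8,MPa
skin,normal,0,0.05,MPa
skin,normal,0.3,2.5,MPa
subcutaneous,normal,0,0.03,MPa
subcutaneous,normal,0.35,1.5,MPa
padding_foam,normal,0,0.06,MPa
padding_foam,normal,0.5,1.2,MPa
padding_foam,tangential,0,0.04,MPa
padding_foam,tangential,0.5,0.8,MPa
", stringsAsFactors = FALSE)
}

#' Build a stiffness curve from a material table
#'
#' @param table Data frame in the layout of [default_material_table()].
#' @param material,direction Row selectors.
#' @param area_mm2 Contact area used to convert stress slopes (MPa) into
#'   lumped force slopes (N per unit strain): `slope_N = slope_MPa * area_mm2`.
#'   Leave `NULL` to keep stress units.
#' @param smoothing_halfwidth Passed to [stiffness_curve()].
#' @return A [stiffness_curve()].
#' @export
material_curve <- function(table, material, direction, area_mm2 = NULL,
                           smoothing_halfwidth = 0.02) {
  rows <- table[table$material == material & table$direction == direction, ,
                drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no entry for material '", material, "', direction '", direction, "'")
  rows <- rows[order(rows$breakpoint_strain), , drop = FALSE]
  sl <- rows$slope
  if (!is.null(area_mm2)) sl <- sl * area_mm2
  stiffness_curve(rows$breakpoint_strain, sl,
                  smoothing_halfwidth = smoothing_halfwidth)
}

#' Lumped spring element from a stiffness in N/mm
#'
#' Convenience constructor for contact-unit layers parameterised the way
#' indentation measurements report them: a baseline stiffness in N/mm that
#' stiffens by `stiffening` beyond `knee_strain` (soft tissue bottoming out
#' under deep compression).  The elastic curve returns force in N as a
#' function of layer strain.
#'
#' @param k_n_per_mm Baseline stiffness, N/mm of layer compression.
#' @param rest_thickness Layer thickness, m.
#' @param knee_strain Strain where stiffening begins (default 0.3).
#' @param stiffening Slope multiplier beyond the knee (default 50).
#' @param tangential_ratio Tangential stiffness as a fraction of normal
#'   (default 0.5).
#' @param damping_normal,damping_tangential Viscous coefficients, N s/m.
#' @param smoothing_halfwidth Strain smoothing halfwidth.
#' @return A [viscoelastic_element()].
#' @export
lumped_element <- function(k_n_per_mm, rest_thickness, knee_strain = 0.3,
                           stiffening = 50, tangential_ratio = 0.5,
                           damping_normal = 0, damping_tangential = 0,
                           smoothing_halfwidth = 0.02) {
  if (k_n_per_mm <= 0) stop("k_n_per_mm must be > 0")
  # N/mm * mm-of-thickness = N per unit strain
  s0 <- k_n_per_mm * rest_thickness * 1e3
  cn <- stiffness_curve(c(0, knee_strain), c(s0, s0 * stiffening),
                        smoothing_halfwidth = smoothing_halfwidth)
  ct <- stiffness_curve(c(0, knee_strain),
                        tangential_ratio * c(s0, s0 * stiffening),
                        smoothing_halfwidth = smoothing_halfwidth)
  viscoelastic_element(cn, ct, damping_normal, damping_tangential,
                       rest_thickness)
}

#' Unit conversion between N/mm and N/m
#'
#' Indentation and design-layer stiffnesses are carried in N/mm (the units
#' in which hand-dorsum stiffness is conventionally reported); the dynamics
#' layer works in SI (N/m).  All conversions go through this one helper.
#'
#' @param k Stiffness value(s).
#' @param from,to `"N/mm"` or `"N/m"`.
#' @return Converted stiffness.
#' @export
convert_stiffness <- function(k, from = c("N/mm", "N/m"), to = c("N/m", "N/mm")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (from == to) return(k)
  if (from == "N/mm") k * 1e3 else k * 1e-3
}
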