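# Parametric axisymmetric geometry of a periderm-dwelling polyp.
#
# All lengths are in millimetres, volumes in mm^3. The coordinate system is
# (r, z) with z = 0 at the domain floor (the sediment surface) and the
# peridermal aperture facing up. The basal part of the periderm is inserted
# into the sediment, so only `exposed_height = periderm_height -
# insertion_depth` of the body protrudes into the fluid.

#' Geometry parameters for the polyp body form
#'
#' Constructs and validates the parameter set describing the rigid outer
#' periderm (a pagoda-shaped tapering shell of revolution) and the moving
#' bowl-shaped subumbrella suspended inside it. All lengths are in mm.
#'
#' @param periderm_height Total height of the periderm, mm.
#' @param periderm_base_radius Radius at the (buried) base, mm.
#' @param aperture_radius Radius of the open top of the periderm, mm. Must be
#'   smaller than `periderm_base_radius`.
#' @param insertion_depth Depth to which the base is inserted into the
#'   sediment, mm. The buried part is removed from the flow domain.
#' @param subumbrella_height Height of the subumbrella bowl, mm.
#' @param subumbrella_max_radius Radius of the bowl at its widest point, mm.
#' @param opening_radius Radius of the bowl's rim opening (the "mouth"), mm.
#' @param ridge_amplitude Amplitude of an optional sinusoidal annular-ridge
#'   perturbation of the periderm flank, mm. 0 gives a smooth periderm.
#' @param ridge_count Number of annular ridges along the exposed flank.
#' @param taper_exponent Shape exponent of the periderm taper; 1 is a cone,
#'   values > 1 give the concave pagoda-like flank.
#' @param belly_fraction Fractional height (0-1) of the bowl's widest point
#'   above its apex.
#' @param min_clearance Smallest admissible radial gap between the
#'   (displaced) bowl wall and the periderm flank, mm. States that squeeze
#'   the gap below this are rejected as geometrically invalid.
#' @param min_opening Smallest admissible rim-opening radius, mm.
#'
#' @return An object of class `geometry_params`.
#' @seealso [canonical_params()] for the default fossil-derived dimensions,
#'   [build_polyp_profile()] to realise the profiles.
#' @export
geometry_params <- function(periderm_height = 2.0,
                            periderm_base_radius = 0.3,
                            aperture_radius = 0.18,
                            insertion_depth = 0.18,
                            subumbrella_height = 0.7,
                            subumbrella_max_radius = 0.12,
                            opening_radius = 0.05,
                            ridge_amplitude = 0,
                            ridge_count = 6L,
                            taper_exponent = 1.2,
                            belly_fraction = 0.55,
                            min_clearance = 0.05,
                            min_opening = 0.02) {
  p <- list(periderm_height = periderm_height,
            periderm_base_radius = periderm_base_radius,
            aperture_radius = aperture_radius,
            insertion_depth = insertion_depth,
            subumbrella_height = subumbrella_height,
            subumbrella_max_radius = subumbrella_max_radius,
            opening_radius = opening_radius,
            ridge_amplitude = ridge_amplitude,
            ridge_count = as.integer(ridge_count),
            taper_exponent = taper_exponent,
            belly_fraction = belly_fraction,
            min_clearance = min_clearance,
            min_opening = min_opening)
  lens <- unlist(p[c("periderm_height", "periderm_base_radius",
                     "aperture_radius", "insertion_depth",
                     "subumbrella_height", "subumbrella_max_radius",
                     "opening_radius", "ridge_amplitude")])
  if (any(!is.finite(lens)) || any(lens < 0))
    stop("all geometric lengths must be finite and >= 0")
  if (p$aperture_radius >= p$periderm_base_radius)
    stop("aperture_radius must be smaller than periderm_base_radius")
  if (p$insertion_depth >= p$periderm_height)
    stop("insertion_depth must be smaller than periderm_height")
  if (p$subumbrella_height >= p$periderm_height - p$insertion_depth)
    stop("subumbrella must fit inside the exposed periderm cavity")
  if (p$opening_radius >= p$subumbrella_max_radius)
    stop("opening_radius must be smaller than subumbrella_max_radius")
  if (p$belly_fraction <= 0 || p$belly_fraction >= 1)
    stop("belly_fraction must lie in (0, 1)")
  structure(p, class = "geometry_params")
}

#' Canonical polyp dimensions
#'
#' Returns the default parameter set for the canonical reconstruction: a
#' periderm 2.0 mm tall and 0.6 mm across at the base (0.3 mm radius),
#' inserted 0.18 mm into the sediment, with a 0.7 mm tall subumbrella bowl.
#' Dimensions not constrained by the fossil material (aperture radius, bowl
#' belly radius, rim-opening radius) carry documented defaults and are all
#' overridable through `...`.
#'
#' @param ... Overrides passed on to [geometry_params()].
#' @return A `geometry_params` object.
#' @export
canonical_params <- function(...) {
  geometry_params(...)
}

#' @export
print.geometry_params <- function(x, ...) {
  cat("polyp geometry parameters (mm):\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# periderm flank radius at height z (mm); vectorised, z in [0, exposed]
periderm_radius_fun <- function(p) {
  He <- p$periderm_height - p$insertion_depth
  force(p)
  function(z) {
    u <- pmin(pmax(z / He, 0), 1)
    r <- p$aperture_radius +
      (p$periderm_base_radius - p$aperture_radius) * (1 - u)^p$taper_exponent
    if (p$ridge_amplitude > 0)
      r <- r + p$ridge_amplitude * sin(2 * pi * p$ridge_count * u)
    r
  }
}

# bowl wall radius at height z (mm); 0 outside the bowl span.
# C1 piecewise sinusoid: 0 at the apex, widest at the belly, necking to the
# rim opening. Single-valued in z by construction.
subumbrella_radius_fun <- function(p, exposed_height) {
  z_apex <- exposed_height - p$subumbrella_height
  xs <- p$belly_fraction
  force(p)
  function(z) {
    xi <- (z - z_apex) / p$subumbrella_height
    r <- numeric(length(z))
    lo <- xi >= 0 & xi <= xs
    hi <- xi > xs & xi <= 1
    r[lo] <- p$subumbrella_max_radius * sin(pi * xi[lo] / (2 * xs))
    r[hi] <- p$opening_radius + (p$subumbrella_max_radius - p$opening_radius) *
      cos(pi * (xi[hi] - xs) / (2 * (1 - xs)))
    r
  }
}

#' Build the polyp profiles
#'
#' Realises the parametric periderm and subumbrella profiles as
#' single-valued radius-versus-height curves and computes the rest cavity
#' volume of the bowl. Rejects parameter sets whose bowl wall approaches the
#' periderm flank closer than `min_clearance`.
#'
#' @param params A [geometry_params()] object.
#' @return An object of class `polyp_geometry` with elements
#'   `periderm_profile(z)` and `subumbrella_profile(z)` (functions of height,
#'   mm in / mm out), `exposed_height`, `z_apex`, `z_rim` (mm) and
#'   `rest_cavity_volume` (mm^3).
#' @export
build_polyp_profile <- function(params) {
  stopifnot(inherits(params, "geometry_params"))
  He <- params$periderm_height - params$insertion_depth
  rp <- periderm_radius_fun(params)
  rs <- subumbrella_radius_fun(params, He)
  z_apex <- He - params$subumbrella_height
  zz <- seq(z_apex, He, length.out = 801)
  gap <- rp(zz) - rs(zz)
  if (min(gap) < params$min_clearance)
    stop(sprintf(
      "bowl wall intersects or crowds the periderm (min gap %.4f mm < %.4f mm)",
      min(gap), params$min_clearance))
  geom <- structure(list(params = params,
                         exposed_height = He,
                         z_apex = z_apex,
                         z_rim = He,
                         periderm_profile = rp,
                         subumbrella_profile = rs,
                         rest_cavity_volume = NA_real_),
                    class = "polyp_geometry")
  geom$rest_cavity_volume <- cavity_volume(geom)
  geom
}

#' @export
print.polyp_geometry <- function(x, ...) {
  cat(sprintf(paste0(
    "polyp geometry: exposed height %.3f mm, apex at z = %.3f mm,\n",
    "  rim opening radius %.3f mm, rest cavity volume %.5f mm^3\n"),
    x$exposed_height, x$z_apex,
    x$subumbrella_profile(x$z_rim), x$rest_cavity_volume))
  invisible(x)
}

#' Cavity volume of the (displaced) subumbrella bowl
#'
#' Volume of revolution of the bowl interior, `pi * integral r(z)^2 dz` over
#' the bowl span, with an optional radial displacement added to the rest
#' profile. This is the water volume the bowl exchanges through its rim
#' opening over a pump cycle, and the reference for flux--volume conservation
#' checks.
#'
#' @param geometry A `polyp_geometry` object.
#' @param displacement Optional radial displacement as a function of height
#'   (mm in, mm out), added to the rest profile. `NULL` means rest state.
#' @param n Number of quadrature points (composite trapezoid).
#' @return Volume in mm^3.
#' @export
cavity_volume <- function(geometry, displacement = NULL, n = 2001) {
  stopifnot(inherits(geometry, "polyp_geometry"))
  zz <- seq(geometry$z_apex, geometry$z_rim, length.out = n)
  r <- geometry$subumbrella_profile(zz)
  if (!is.null(displacement)) {
    r <- r + displacement(zz)
    if (any(r < 0))
      stop("displaced bowl profile is self-intersecting (negative radius)")
    gap <- geometry$periderm_profile(zz) - r
    if (min(gap) < geometry$params$min_clearance)
      stop("displaced bowl profile crowds the periderm wall")
  }
  hstep <- (geometry$z_rim - geometry$z_apex) / (n - 1)
  pi * (sum(r^2) - (r[1]^2 + r[n]^2) / 2) * hstep
}

#' Export profiles as a two-column table
#'
#' @param geometry A `polyp_geometry` object.
#' @param which `"periderm"` or `"subumbrella"`.
#' @param n Number of samples.
#' @return A data.frame with columns `z_mm`, `r_mm`.
#' @export
profile_table <- function(geometry, which = c("periderm", "subumbrella"),
                          n = 201) {
  which <- match.arg(which)
  if (which == "periderm") {
    z <- seq(0, geometry$exposed_height, length.out = n)
    r <- geometry$periderm_profile(z)
  } else {
    z <- seq(geometry$z_apex, geometry$z_rim, length.out = n)
    r <- geometry$subumbrella_profile(z)
  }
  data.frame(z_mm = z, r_mm = r)
}
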