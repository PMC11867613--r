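# Prescribed kinematics of the subumbrella.
#
# The bowl wall moves radially only: displaced profile
#   r(z, t) = r0(z) + amplitude_scale * A(z) * s(t)
# where A(z) is a cubic-spline amplitude profile anchored to zero at the
# bowl apex and s(t) is a C1 temporal ramp running 0 -> 1 over the
# expansion phase and back to 0 over the contraction phase. The axial and
# azimuthal surface velocities are identically zero.

#' Scenario shorthand for expansion:contraction time ratios
#'
#' Maps a label such as `"3:1"` to the phase durations in seconds
#' (contraction is fixed at 1 s in the canonical scenarios).
#'
#' @param label Character like `"1:1"`, `"2:1"`, `"3:1"`, `"4:1"`.
#' @return Named numeric vector `c(T_exp = , T_con = )`.
#' @export
parse_ratio <- function(label) {
  parts <- suppressWarnings(as.numeric(strsplit(label, ":", fixed = TRUE)[[1]]))
  if (length(parts) != 2 || any(!is.finite(parts)) || any(parts <= 0))
    stop(sprintf("invalid ratio label '%s'", label))
  c(T_exp = parts[1], T_con = parts[2])
}

#' Temporal ramp of the pump cycle
#'
#' Builds the C1 ramp `s(t)` and its rate for one expansion/contraction
#' cycle. The rate on each phase is a smooth bump that vanishes with zero
#' slope at the phase endpoints; its peak sits at a configurable fraction of
#' the phase. The bump is the density of a Beta(4f+1, 4(1-f)+1) variable in
#' normalised phase time, so `s` is the corresponding distribution function
#' and the rate peak lands exactly at fraction `f` of the phase.
#'
#' @param T_exp,T_con Phase durations, s (> 0).
#' @param peak_fraction_exp Fraction of the expansion phase at which the
#'   expansion rate peaks (default 0.6; with `T_exp` = 3 s the peak is at
#'   1.8 s).
#' @param peak_fraction_con Same for the contraction phase (default 0.5;
#'   with `T_exp` = 3 s the contraction-rate peak is at 3.5 s).
#' @return List with functions `s(t)`, `dsdt(t)` (defined on one cycle,
#'   cyclic outside), and `T_cycle`.
#' @export
temporal_profile <- function(T_exp, T_con,
                             peak_fraction_exp = 0.6,
                             peak_fraction_con = 0.5) {
  if (!is.finite(T_exp) || !is.finite(T_con) || T_exp <= 0 || T_con <= 0)
    stop("phase durations must be positive")
  for (f in c(peak_fraction_exp, peak_fraction_con))
    if (f <= 0.25 || f >= 0.75)
      stop("peak fractions must lie in (0.25, 0.75) for a C1 bump")
  ae <- 4 * peak_fraction_exp + 1; be <- 4 * (1 - peak_fraction_exp) + 1
  ac <- 4 * peak_fraction_con + 1; bc <- 4 * (1 - peak_fraction_con) + 1
  Tc <- T_exp + T_con
  s <- function(t) {
    t <- t %% Tc
    ifelse(t <= T_exp,
           stats::pbeta(t / T_exp, ae, be),
           1 - stats::pbeta((t - T_exp) / T_con, ac, bc))
  }
  dsdt <- function(t) {
    t <- t %% Tc
    ifelse(t <= T_exp,
           stats::dbeta(t / T_exp, ae, be) / T_exp,
           -stats::dbeta((t - T_exp) / T_con, ac, bc) / T_con)
  }
  list(s = s, dsdt = dsdt, T_cycle = Tc,
       t_peak_exp = peak_fraction_exp * T_exp,
       t_peak_con = T_exp + peak_fraction_con * T_con)
}

#' Spline amplitude profile A(z)
#'
#' Natural cubic spline through the control points, clamped to zero outside
#' their span. The first control point is the bowl apex anchor and must have
#' amplitude exactly 0 (the apex is a fixed constraint).
#'
#' @param control_points Two-column matrix or data.frame `(z, A)`, z strictly
#'   increasing, both in mm.
#' @return A function `A(z)` (mm in, mm out).
#' @export
amplitude_profile <- function(control_points) {
  cp <- as.matrix(control_points)
  if (ncol(cp) != 2) stop("control_points must have two columns (z, A)")
  z <- cp[, 1]; a <- cp[, 2]
  if (anyDuplicated(z)) stop("duplicate z values in control points")
  if (is.unsorted(z, strictly = TRUE)) stop("z values must be strictly increasing")
  if (a[1] != 0) stop("the apex anchor (first control point) must have A = 0")
  if (length(z) == 1) return(function(zz) numeric(length(zz)))
  sp <- stats::splinefun(z, a, method = "natural")
  zmin <- z[1]; zmax <- z[length(z)]
  function(zz) ifelse(zz >= zmin & zz <= zmax, sp(zz), 0)
}

#' Default amplitude control points for a geometry
#'
#' Outward displacement at mid-bowl (the belly region widens and draws water
#' in through the rim opening) combined with a slight inward displacement at
#' the rim (the mouth narrows towards full expansion).
#'
#' @param geometry A `polyp_geometry` object.
#' @return A 3 x 2 matrix of `(z, A)` control points, mm.
#' @export
default_control_points <- function(geometry) {
  cbind(z = c(geometry$z_apex, (geometry$z_apex + geometry$z_rim) / 2,
              geometry$z_rim),
        A = c(0, 0.05, -0.02))
}

#' Motion specification for the pump cycle
#'
#' @param T_exp,T_con Phase durations, s. Canonical scenarios use
#'   `T_exp` in 1..4 s with `T_con` fixed at 1 s.
#' @param amplitude_control_points Control points for [amplitude_profile()];
#'   `NULL` selects [default_control_points()] of the geometry in use.
#' @param peak_fraction_exp,peak_fraction_con See [temporal_profile()].
#' @param amplitude_scale Dimensionless multiplier applied to the amplitude
#'   profile. The default is frozen at 0.45, the largest value (with a
#'   safety margin) for which the canonical geometry remains valid over the
#'   whole cycle; see [amplitude_scale_limit()].
#' @return An object of class `motion_spec`.
#' @export
motion_spec <- function(T_exp = 1, T_con = 1,
                        amplitude_control_points = NULL,
                        peak_fraction_exp = 0.6,
                        peak_fraction_con = 0.5,
                        amplitude_scale = 0.45) {
  tp <- temporal_profile(T_exp, T_con, peak_fraction_exp, peak_fraction_con)
  structure(list(T_exp = T_exp, T_con = T_con,
                 T_cycle = tp$T_cycle,
                 amplitude_control_points = amplitude_control_points,
                 peak_fraction_exp = peak_fraction_exp,
                 peak_fraction_con = peak_fraction_con,
                 amplitude_scale = amplitude_scale,
                 temporal = tp),
            class = "motion_spec")
}

#' @export
print.motion_spec <- function(x, ...) {
  cat(sprintf(
    "motion spec: expansion %.3g s, contraction %.3g s, amplitude scale %.3g\n",
    x$T_exp, x$T_con, x$amplitude_scale))
  invisible(x)
}

# resolve the amplitude function for (motion, geometry)
motion_amplitude <- function(motion, geometry) {
  cp <- motion$amplitude_control_points
  if (is.null(cp)) cp <- default_control_points(geometry)
  amplitude_profile(cp)
}

#' Displaced subumbrella surface at time t
#'
#' Evaluates the prescribed boundary state: displaced bowl profile,
#' radial surface velocity, and rim-opening diameter. States that cross the
#' periderm wall, close the rim below `min_opening`, or drive the profile
#' negative are rejected as geometrically invalid.
#'
#' @param geometry A `polyp_geometry` object.
#' @param motion A `motion_spec`.
#' @param t Time within the cycle, s.
#' @return An object of class `boundary_state`: `profile(z)` (mm),
#'   `velocity(z)` (radial surface velocity, m/s), `opening_diameter` (mm),
#'   plus the ramp value `s` and rate `rate` (1/s) at `t`.
#' @export
displaced_surface <- function(geometry, motion, t) {
  stopifnot(inherits(geometry, "polyp_geometry"), inherits(motion, "motion_spec"))
  A <- motion_amplitude(motion, geometry)
  sc <- motion$amplitude_scale
  sv <- motion$temporal$s(t)
  rate <- motion$temporal$dsdt(t)
  r0 <- geometry$subumbrella_profile
  prof <- function(z) r0(z) + sc * A(z) * sv
  vel <- function(z) sc * A(z) * rate * 1e-3     # mm/s -> m/s

  zz <- seq(geometry$z_apex, geometry$z_rim, length.out = 600)
  rd <- prof(zz)
  if (any(rd < 0))
    stop(sprintf("invalid boundary state at t = %.3f s: negative bowl radius", t))
  gap <- geometry$periderm_profile(zz) - rd
  if (min(gap) < geometry$params$min_clearance)
    stop(sprintf(
      "invalid boundary state at t = %.3f s: bowl crowds the periderm (gap %.4f mm)",
      t, min(gap)))
  rim <- prof(geometry$z_rim)
  if (rim < geometry$params$min_opening)
    stop(sprintf("invalid boundary state at t = %.3f s: rim opening closed", t))

  structure(list(time = t, s = sv, rate = rate,
                 profile = prof, velocity = vel,
                 opening_diameter = 2 * rim,
                 geometry = geometry, motion = motion),
            class = "boundary_state")
}

#' Rim-opening diameter of a boundary state
#'
#' @param state A `boundary_state`.
#' @return Diameter of the bowl's rim opening, mm.
#' @export
opening_diameter <- function(state) {
  stopifnot(inherits(state, "boundary_state"))
  state$opening_diameter
}

#' Largest admissible amplitude scale for a geometry
#'
#' Bisects for the largest `amplitude_scale` for which every state of the
#' cycle (s in 0..1 with the given amplitude profile) keeps the bowl clear
#' of the periderm, the rim open, and the profile non-negative. Used once,
#' during development, to freeze the default scale in [motion_spec()].
#'
#' @param geometry A `polyp_geometry` object.
#' @param control_points Amplitude control points (default
#'   [default_control_points()]).
#' @param tol Bisection tolerance on the scale.
#' @return The limiting scale (dimensionless).
#' @export
amplitude_scale_limit <- function(geometry, control_points = NULL, tol = 1e-3) {
  if (is.null(control_points)) control_points <- default_control_points(geometry)
  A <- amplitude_profile(control_points)
  zz <- seq(geometry$z_apex, geometry$z_rim, length.out = 600)
  r0 <- geometry$subumbrella_profile(zz)
  rp <- geometry$periderm_profile(zz)
  ok <- function(sc) {
    for (sv in seq(0, 1, length.out = 21)) {
      rd <- r0 + sc * A(zz) * sv
      if (any(rd < 0)) return(FALSE)
      if (min(rp - rd) < geometry$params$min_clearance) return(FALSE)
      if (rd[length(rd)] < geometry$params$min_opening) return(FALSE)
    }
    TRUE
  }
  lo <- 0; hi <- 1
  while (ok(hi)) { lo <- hi; hi <- 2 * hi; if (hi > 1e3) return(hi) }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (ok(mid)) lo <- mid else hi <- mid
  }
  lo
}
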