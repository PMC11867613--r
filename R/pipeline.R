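# Scenario driver: full expansion/contraction cycles, cut-point sampling,
# and result persistence.

#' Cut-point specification
#'
#' Axial sampling stations above the peridermal aperture. The defaults place
#' 10 points on the symmetry axis from z = 2.05 mm to z = 2.5 mm with
#' 0.05 mm spacing.
#'
#' @param z_min,z_max,spacing Axial range and spacing, mm.
#' @param r Radial position of the points, mm (default 0, on the axis).
#' @return An object of class `cut_point_spec`.
#' @export
cut_point_spec <- function(z_min = 2.05, z_max = 2.5, spacing = 0.05, r = 0) {
  z <- seq(z_min, z_max, by = spacing)
  structure(list(z_min = z_min, z_max = z_max, spacing = spacing, r = r,
                 z = z), class = "cut_point_spec")
}

#' Scenario configuration
#'
#' Bundles everything one simulated pump cycle needs: geometry, motion,
#' fluid, solver, grid, output cadence and sampling stations.
#'
#' @param geometry A [geometry_params()] object.
#' @param motion A [motion_spec()] object.
#' @param fluid A [fluid_props()] object.
#' @param solver A [solver_config()] object.
#' @param grid A [domain_grid()] object.
#' @param snapshot_interval Output cadence, s.
#' @param cut_points A [cut_point_spec()] object.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(geometry = canonical_params(),
                            motion = motion_spec(),
                            fluid = fluid_props(),
                            solver = solver_config(),
                            grid = domain_grid(),
                            snapshot_interval = 0.05,
                            cut_points = cut_point_spec()) {
  stopifnot(inherits(geometry, "geometry_params"),
            inherits(motion, "motion_spec"),
            inherits(cut_points, "cut_point_spec"))
  if (snapshot_interval <= 0) stop("snapshot_interval must be > 0")
  structure(list(geometry = geometry, motion = motion, fluid = fluid,
                 solver = solver, grid = grid,
                 snapshot_interval = snapshot_interval,
                 cut_points = cut_points),
            class = "scenario_config")
}

# rebuild a config's motion with new phase durations
set_ratio <- function(config, label) {
  tc <- parse_ratio(label)
  m <- config$motion
  config$motion <- motion_spec(T_exp = tc[["T_exp"]], T_con = tc[["T_con"]],
                               amplitude_control_points = m$amplitude_control_points,
                               peak_fraction_exp = m$peak_fraction_exp,
                               peak_fraction_con = m$peak_fraction_con,
                               amplitude_scale = m$amplitude_scale)
  config
}

# analytic cavity-volume rate (mm^3/s) at time t
cavity_volume_rate <- function(geometry, motion, t, n = 2001) {
  A <- motion_amplitude(motion, geometry)
  sc <- motion$amplitude_scale
  sv <- motion$temporal$s(t)
  rate <- motion$temporal$dsdt(t)
  zz <- seq(geometry$z_apex, geometry$z_rim, length.out = n)
  rd <- geometry$subumbrella_profile(zz) + sc * A(zz) * sv
  integrand <- 2 * pi * rd * sc * A(zz) * rate
  hstep <- (geometry$z_rim - geometry$z_apex) / (n - 1)
  sum(integrand) * hstep - (integrand[1] + integrand[n]) / 2 * hstep
}

# zero flow field (rest state shortcut; the Stokes problem is trivially 0
# when every boundary velocity vanishes)
zero_field <- function(mask, time) {
  g <- mask$grid
  structure(list(time = time,
                 u_r = matrix(0, g$nr, g$nz),
                 u_z = matrix(0, g$nr, g$nz),
                 p = matrix(0, g$nr, g$nz),
                 grid = g, chi = mask$chi,
                 div_max = 0, penal_error = 0, uzawa_iters = 0),
            class = "flow_field")
}

# one snapshot: boundary state -> mask -> field
solve_snapshot <- function(geometry, config, t) {
  bstate <- displaced_surface(geometry, config$motion, t)
  mask <- rasterize_solid(geometry, bstate, config$grid)
  if (mask$peak_speed == 0) return(zero_field(mask, t))
  solve_quasi_steady(mask, config$fluid, config$solver, time = t)
}

#' Interpolate velocity at points
#'
#' Bilinear interpolation of the staggered velocity components at arbitrary
#' `(r, z)` positions, honouring the axis symmetry (u_r odd, u_z even in r)
#' and the no-slip floor.
#'
#' @param field A `flow_field`.
#' @param r,z Coordinates, mm (vectorised).
#' @return List with components `u_r`, `u_z` in m/s.
#' @export
field_velocity_at <- function(field, r, z) {
  g <- field$grid
  h <- g$h
  n <- max(length(r), length(z))
  r <- rep_len(r, n); z <- rep_len(z, n)
  if (any(r < 0 | r > g$radius_extent | z < 0 | z > g$height_extent))
    stop("interpolation point outside the domain")

  # u_r on (i*h, (j-1/2)*h), with u_r = 0 at the axis face r = 0
  urmat <- rbind(0, field$u_r)              # prepend axis face
  ri <- pmin(pmax(r / h, 0), g$nr)          # fractional face index (0-based)
  i0 <- pmin(floor(ri), g$nr - 1); wi <- ri - i0
  zj <- pmin(pmax(z / h - 0.5, 0), g$nz - 1)
  j0 <- pmin(floor(zj), g$nz - 2); wj <- zj - j0
  idx <- function(m, i, j) m[cbind(i, j)]
  ur <- (1 - wi) * (1 - wj) * idx(urmat, i0 + 1, j0 + 1) +
    wi * (1 - wj) * idx(urmat, i0 + 2, j0 + 1) +
    (1 - wi) * wj * idx(urmat, i0 + 1, j0 + 2) +
    wi * wj * idx(urmat, i0 + 2, j0 + 2)

  # u_z on ((i-1/2)*h, j*h), even in r, zero on the floor face z = 0
  uzmat <- rbind(field$u_z[1, ], field$u_z)  # mirror ghost column at r = -h/2
  uzmat <- cbind(0, uzmat)                   # floor face z = 0
  ri <- pmin(pmax(r / h + 0.5, 0), g$nr)     # index into mirrored columns
  i0 <- pmin(floor(ri), g$nr - 1); wi <- ri - i0
  zj <- pmin(pmax(z / h, 0), g$nz)
  j0 <- pmin(floor(zj), g$nz - 1); wj <- zj - j0
  uz <- (1 - wi) * (1 - wj) * idx(uzmat, i0 + 1, j0 + 1) +
    wi * (1 - wj) * idx(uzmat, i0 + 2, j0 + 1) +
    (1 - wi) * wj * idx(uzmat, i0 + 1, j0 + 2) +
    wi * wj * idx(uzmat, i0 + 2, j0 + 2)

  list(u_r = ur, u_z = uz)
}

#' Sample flow speeds at the cut points
#'
#' @param field A `flow_field`.
#' @param spec A [cut_point_spec()] (or a numeric vector of z positions on
#'   the axis, mm).
#' @return Numeric vector of speed magnitudes, m/s, one per point.
#' @export
sample_cut_points <- function(field, spec = cut_point_spec()) {
  if (is.numeric(spec)) spec <- list(z = spec, r = 0)
  g <- field$grid
  zp <- spec$z; rp <- rep_len(spec$r, length(zp))
  ci <- pmin(pmax(ceiling(rp / g$h), 1), g$nr)
  cj <- pmin(pmax(ceiling(zp / g$h), 1), g$nz)
  if (any(field$chi[cbind(ci, cj)] >= 0.5))
    stop("cut point lies inside the solid body")
  v <- field_velocity_at(field, rp, zp)
  sqrt(v$u_r^2 + v$u_z^2)
}

#' Run one pump-cycle scenario
#'
#' Steps through one full expansion/contraction cycle at the configured
#' snapshot cadence. Every snapshot is an independent quasi-steady Stokes
#' solve around the instantaneous displaced geometry; there is no randomness
#' anywhere and two runs of the same configuration are identical.
#'
#' @param config A [scenario_config()].
#' @param ratio Optional scenario shorthand (e.g. `"3:1"`) overriding the
#'   configured phase durations.
#' @param store_fields Keep the full flow-field snapshots in the result
#'   (needed for vorticity work); otherwise only traces and kinematics.
#' @param verbose Print per-snapshot progress with solver diagnostics.
#' @return An object of class `simulation_result`: `label`, `times`,
#'   `traces` (time x cut point speed matrix, m/s), `kinematics`
#'   (data.frame), `fields` (list of `flow_field` or NULL), `config`.
#' @export
run_scenario <- function(config, ratio = NULL, store_fields = TRUE,
                         verbose = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(ratio)) config <- set_ratio(config, ratio)
  geometry <- build_polyp_profile(config$geometry)
  motion <- config$motion
  times <- seq(0, motion$T_cycle, by = config$snapshot_interval)
  if (times[length(times)] < motion$T_cycle) times <- c(times, motion$T_cycle)
  zpts <- config$cut_points$z
  traces <- matrix(NA_real_, length(times), length(zpts))
  colnames(traces) <- sprintf("z%.2f", zpts)
  kin <- data.frame(t_s = times, s = NA_real_, rate_1_s = NA_real_,
                    opening_diameter_mm = NA_real_,
                    cavity_volume_mm3 = NA_real_,
                    dVdt_mm3_s = NA_real_,
                    aperture_flux_mm3_s = NA_real_)
  fields <- if (store_fields) vector("list", length(times)) else NULL

  A <- motion_amplitude(motion, geometry)
  sc <- motion$amplitude_scale
  for (k in seq_along(times)) {
    t <- times[k]
    field <- tryCatch(solve_snapshot(geometry, config, t),
                      error = function(e)
                        stop(sprintf("snapshot at t = %.3f s failed: %s",
                                     t, conditionMessage(e)), call. = FALSE))
    traces[k, ] <- sample_cut_points(field, config$cut_points)
    sv <- motion$temporal$s(t)
    kin$s[k] <- sv
    kin$rate_1_s[k] <- motion$temporal$dsdt(t)
    kin$opening_diameter_mm[k] <-
      2 * (geometry$subumbrella_profile(geometry$z_rim) +
             sc * A(geometry$z_rim) * sv)
    kin$cavity_volume_mm3[k] <-
      cavity_volume(geometry, function(z) sc * A(z) * sv)
    kin$dVdt_mm3_s[k] <- cavity_volume_rate(geometry, motion, t)
    kin$aperture_flux_mm3_s[k] <- aperture_flux(field, geometry)
    if (store_fields) fields[[k]] <- field
    if (verbose)
      message(sprintf(
        "  t = %6.3f s  s = %.3f  max cut speed %.3e m/s  div %.2e  penal %.2e (%d it)",
        t, sv, max(traces[k, ]), field$div_max, field$penal_error,
        field$uzawa_iters))
  }
  structure(list(label = sprintf("%g:%g", motion$T_exp, motion$T_con),
                 times = times, traces = traces, kinematics = kin,
                 fields = fields, geometry = geometry, config = config),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "scenario %s: %d snapshots over %.3g s; peak cut-point speed %.3g m/s\n",
    x$label, length(x$times), max(x$times), max(x$traces)))
  invisible(x)
}

#' Run a sweep over expansion:contraction ratios
#'
#' @param ratios Character vector of scenario labels (e.g.
#'   `c("1:1", "2:1", "3:1", "4:1")`).
#' @param config Base [scenario_config()]; all other settings are shared.
#' @param ... Passed to [run_scenario()].
#' @return List of `simulation_result`, named by ratio.
#' @export
run_sweep <- function(ratios, config = scenario_config(), ...) {
  res <- lapply(ratios, function(rt) run_scenario(config, ratio = rt, ...))
  names(res) <- ratios
  res
}

#' Speeds at the cut points for arbitrary times
#'
#' Solves additional snapshots (e.g. to refine a peak location beyond the
#' snapshot cadence).
#'
#' @param config A [scenario_config()] (with the desired motion already set).
#' @param times Times within the cycle, s.
#' @return Matrix time x cut point of speeds, m/s.
#' @export
snapshot_speeds <- function(config, times) {
  geometry <- build_polyp_profile(config$geometry)
  out <- t(vapply(times, function(t) {
    field <- solve_snapshot(geometry, config, t)
    sample_cut_points(field, config$cut_points)
  }, numeric(length(config$cut_points$z))))
  rownames(out) <- sprintf("%.3f", times)
  colnames(out) <- sprintf("z%.2f", config$cut_points$z)
  out
}

#' Export a simulation result to disk
#'
#' Writes the cut-point traces and kinematic record as CSV, a subset of the
#' field snapshots as legacy VTK, and a YAML manifest echoing the full
#' configuration.
#'
#' @param result A `simulation_result`.
#' @param directory Target directory (created if needed).
#' @param field_times Times (s) whose snapshots are exported as VTK; default
#'   five evenly spaced snapshots (ignored when fields were not stored).
#' @return Invisibly, the paths written.
#' @export
export_results <- function(result, directory,
                           field_times = NULL) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  paths <- character(0)

  tr <- data.frame(t_s = result$times, result$traces, check.names = FALSE)
  p <- file.path(directory, "traces.csv")
  utils::write.csv(tr, p, row.names = FALSE)
  paths <- c(paths, p)

  p <- file.path(directory, "kinematics.csv")
  utils::write.csv(result$kinematics, p, row.names = FALSE)
  paths <- c(paths, p)

  if (!is.null(result$fields)) {
    if (is.null(field_times))
      field_times <- result$times[unique(round(seq(1, length(result$times),
                                                   length.out = 5)))]
    for (t in field_times) {
      k <- which.min(abs(result$times - t))
      p <- file.path(directory, sprintf("field_t%07.3fs.vtk", result$times[k]))
      write_vtk_field(result$fields[[k]], p)
      paths <- c(paths, p)
    }
  }

  p <- file.path(directory, "manifest.yaml")
  yaml::write_yaml(c(list(package = "polypflow",
                          version = as.character(utils::packageVersion("polypflow")),
                          scenario = result$label),
                     scenario_config_to_list(result$config)), p)
  paths <- c(paths, p)
  invisible(paths)
}

#' Read exported cut-point traces
#'
#' @param path Path to a `traces.csv` written by [export_results()].
#' @return List with `times` and `traces` (matrix).
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  list(times = df$t_s, traces = as.matrix(df[, -1, drop = FALSE]))
}
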