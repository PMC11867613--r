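# Structured-text (YAML) serialization of scenario configurations.

#' Convert a scenario configuration to a plain list
#'
#' @param config A [scenario_config()].
#' @return A nested list of plain vectors suitable for YAML.
#' @export
scenario_config_to_list <- function(config) {
  m <- config$motion
  cp <- m$amplitude_control_points
  list(geometry = unclass(config$geometry),
       motion = list(T_exp = m$T_exp, T_con = m$T_con,
                     peak_fraction_exp = m$peak_fraction_exp,
                     peak_fraction_con = m$peak_fraction_con,
                     amplitude_scale = m$amplitude_scale,
                     amplitude_control_points =
                       if (is.null(cp)) NULL else
                         list(z = as.numeric(cp[, 1]), A = as.numeric(cp[, 2]))),
       fluid = unclass(config$fluid),
       solver = unclass(config$solver),
       grid = list(radius_extent = config$grid$radius_extent,
                   height_extent = config$grid$height_extent,
                   nr = config$grid$nr, nz = config$grid$nz),
       snapshot_interval = config$snapshot_interval,
       cut_points = list(z_min = config$cut_points$z_min,
                         z_max = config$cut_points$z_max,
                         spacing = config$cut_points$spacing,
                         r = config$cut_points$r))
}

#' Build a scenario configuration from a plain list
#'
#' Missing sections fall back to the package defaults.
#'
#' @param x A list as produced by [scenario_config_to_list()] (for example
#'   parsed from YAML).
#' @return A [scenario_config()].
#' @export
scenario_config_from_list <- function(x) {
  geometry <- do.call(geometry_params, x$geometry %||% list())
  mo <- x$motion %||% list()
  if (!is.null(mo$amplitude_control_points))
    mo$amplitude_control_points <- cbind(z = mo$amplitude_control_points$z,
                                         A = mo$amplitude_control_points$A)
  motion <- do.call(motion_spec, mo)
  fluid <- do.call(fluid_props, x$fluid %||% list())
  solver <- do.call(solver_config, x$solver %||% list())
  grid <- do.call(domain_grid, x$grid %||% list())
  cps <- do.call(cut_point_spec, x$cut_points %||% list())
  scenario_config(geometry = geometry, motion = motion, fluid = fluid,
                  solver = solver, grid = grid,
                  snapshot_interval = x$snapshot_interval %||% 0.05,
                  cut_points = cps)
}

#' Read / write scenario configurations as YAML
#'
#' @param path File path.
#' @return `read_scenario_config` returns a [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  scenario_config_from_list(yaml::read_yaml(path))
}

#' @rdname read_scenario_config
#' @param config A [scenario_config()] to write.
#' @export
write_scenario_config <- function(config, path) {
  yaml::write_yaml(scenario_config_to_list(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
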