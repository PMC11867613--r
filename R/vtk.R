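# Legacy-VTK export of flow fields (structured points, ASCII).
# Velocities are interpolated to cell centres; coordinates are in mm,
# velocities in m/s, pressure in Pa.

#' Write a flow field as a legacy VTK structured grid
#'
#' @param field A `flow_field`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_vtk_field <- function(field, path) {
  g <- field$grid
  nr <- g$nr; nz <- g$nz
  urf <- rbind(0, field$u_r)
  uc_r <- (urf[-(nr + 1), , drop = FALSE] + urf[-1, , drop = FALSE]) / 2
  uzf <- cbind(0, field$u_z)
  uc_z <- (uzf[, -(nz + 1), drop = FALSE] + uzf[, -1, drop = FALSE]) / 2
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("polypflow flow field t=%.6f s (r-z plane, mm, m/s, Pa)",
                       field$time),
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nr, nz),
               sprintf("ORIGIN %.9g %.9g 0", g$h / 2, g$h / 2),
               sprintf("SPACING %.9g %.9g %.9g", g$h, g$h, g$h),
               sprintf("POINT_DATA %d", nr * nz),
               "VECTORS velocity double"), con)
  vel <- cbind(as.vector(uc_r), as.vector(uc_z), 0)
  writeLines(apply(vel, 1, function(x) paste(format(x, digits = 9),
                                             collapse = " ")), con)
  writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(as.vector(field$p), digits = 9), con)
  writeLines(c("SCALARS solid double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(as.vector(field$chi), digits = 3), con)
  invisible(path)
}

#' Read back a VTK flow-field export
#'
#' Minimal reader for the files written by [write_vtk_field()].
#'
#' @param path File path.
#' @return List with `dims`, `spacing`, matrices `u_r`, `u_z`, `p` at cell
#'   centres.
#' @export
read_vtk_field <- function(path) {
  lines <- readLines(path)
  dimline <- grep("^DIMENSIONS", lines, value = TRUE)
  dims <- as.integer(strsplit(dimline, "\\s+")[[1]][2:3])
  spacing <- as.numeric(strsplit(grep("^SPACING", lines, value = TRUE),
                                 "\\s+")[[1]][2])
  n <- prod(dims)
  vstart <- grep("^VECTORS velocity", lines) + 1
  vel <- do.call(rbind, lapply(lines[vstart:(vstart + n - 1)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  pstart <- grep("^SCALARS pressure", lines) + 2
  p <- as.numeric(lines[pstart:(pstart + n - 1)])
  list(dims = dims, spacing = spacing,
       u_r = matrix(vel[, 1], dims[1], dims[2]),
       u_z = matrix(vel[, 2], dims[1], dims[2]),
       p = matrix(p, dims[1], dims[2]))
}

#' Export a flow field as flat CSV
#'
#' Cell-centred table with columns `r_mm`, `z_mm`, `u_r`, `u_z` (m/s) and
#' `p` (Pa).
#'
#' @param field A `flow_field`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_field_csv <- function(field, path) {
  g <- field$grid
  nr <- g$nr; nz <- g$nz
  urf <- rbind(0, field$u_r)
  uc_r <- (urf[-(nr + 1), , drop = FALSE] + urf[-1, , drop = FALSE]) / 2
  uzf <- cbind(0, field$u_z)
  uc_z <- (uzf[, -(nz + 1), drop = FALSE] + uzf[, -1, drop = FALSE]) / 2
  df <- data.frame(r_mm = rep(g$r_centers, nz),
                   z_mm = rep(g$z_centers, each = nr),
                   u_r = as.vector(uc_r), u_z = as.vector(uc_z),
                   p = as.vector(field$p))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
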