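# Computational grid and rasterization of the solid body.
#
# The 3D cuboid flow domain is reduced to an axisymmetric cylinder; the grid
# is a uniform staggered (MAC) arrangement in (r, z):
#   - radial velocity u_r on radial faces  (i*h, (j-1/2)*h), i = 1..nr
#   - axial velocity  u_z on axial faces   ((i-1/2)*h, j*h), j = 1..nz
#   - pressure        p   at cell centres  ((i-1/2)*h, (j-1/2)*h)
# The axis face u_r(0, z) = 0 and the floor face u_z(r, 0) = 0 are implied
# and not stored.

#' Uniform staggered grid for the axisymmetric flow domain
#'
#' @param radius_extent Radial extent of the domain, mm (default 5, the
#'   axisymmetric reduction of a 10 mm wide cuboid).
#' @param height_extent Axial extent, mm (default 10).
#' @param nr,nz Number of cells radially and axially. The defaults give
#'   square cells of about 41.7 um.
#' @return An object of class `domain_grid`.
#' @export
domain_grid <- function(radius_extent = 5, height_extent = 10,
                        nr = 120, nz = 240) {
  if (radius_extent <= 0 || height_extent <= 0) stop("extents must be > 0")
  nr <- as.integer(nr); nz <- as.integer(nz)
  hr <- radius_extent / nr
  hz <- height_extent / nz
  if (abs(hr - hz) > 1e-12 * hr)
    stop("grid cells must be square: radius_extent/nr must equal height_extent/nz")
  structure(list(radius_extent = radius_extent,
                 height_extent = height_extent,
                 nr = nr, nz = nz, h = hr,
                 staggering = "MAC r-z",
                 r_centers = (seq_len(nr) - 0.5) * hr,
                 z_centers = (seq_len(nz) - 0.5) * hz,
                 r_faces = seq_len(nr) * hr,
                 z_faces = seq_len(nz) * hz),
            class = "domain_grid")
}

#' @export
print.domain_grid <- function(x, ...) {
  cat(sprintf("staggered grid: %d x %d cells over %.3g x %.3g mm (h = %.4g mm)\n",
              x$nr, x$nz, x$radius_extent, x$height_extent, x$h))
  invisible(x)
}

#' Refine a grid by a linear factor
#'
#' @param grid A `domain_grid`.
#' @param factor Linear refinement factor (> 1 refines).
#' @return A new `domain_grid` over the same extents.
#' @export
refine_grid <- function(grid, factor = sqrt(2)) {
  nr <- round(grid$nr * factor)
  domain_grid(grid$radius_extent, grid$height_extent,
              nr = nr, nz = round(nr * grid$height_extent / grid$radius_extent))
}

#' Rasterize the solid body onto the grid
#'
#' Marks as solid every cell whose centre lies inside the polyp body: the
#' region bounded outside by the periderm flank and inside by the (displaced)
#' subumbrella bowl, i.e. periderm shell plus the soft tissue between bowl
#' and shell. The bowl interior (the pumping cavity) and everything outside
#' the periderm is fluid. Faces adjacent to a solid cell carry the embedded
#' boundary velocity: zero on the rigid periderm, and on the moving bowl wall
#' the radial surface velocity extended as the solenoidal field
#' `u_r(r, z) = v_surf(z) * r_s(z) / r`, which preserves the volume flux
#' driven into the cavity independent of the stair-step rasterization.
#'
#' @param geometry A `polyp_geometry` object.
#' @param boundary A `boundary_state` from [displaced_surface()], or `NULL`
#'   for the rest state (zero motion).
#' @param grid A `domain_grid`. The displaced gap between bowl and periderm
#'   and the rim opening must span at least about one cell; narrower
#'   configurations are signalled as under-resolved.
#' @return An object of class `solid_mask` with the cell indicator `chi`
#'   (nr x nz), face indicators, and prescribed face velocities in m/s.
#' @export
rasterize_solid <- function(geometry, boundary = NULL, grid = domain_grid()) {
  stopifnot(inherits(geometry, "polyp_geometry"), inherits(grid, "domain_grid"))
  nr <- grid$nr; nz <- grid$nz; h <- grid$h
  He <- geometry$exposed_height
  rp <- geometry$periderm_profile

  if (is.null(boundary)) {
    rs_disp <- geometry$subumbrella_profile
    vsurf <- function(z) numeric(length(z))   # m/s
  } else {
    stopifnot(inherits(boundary, "boundary_state"))
    rs_disp <- boundary$profile
    vsurf <- boundary$velocity
  }

  # resolvability: rim opening and bowl-periderm gap vs cell size
  zz <- seq(geometry$z_apex, geometry$z_rim, length.out = 400)
  gap <- rp(zz) - rs_disp(zz)
  rim <- rs_disp(geometry$z_rim)
  if (rim < 0.8 * h)
    stop(sprintf("under-resolved geometry: rim opening %.4f mm < 0.8 cells", rim))
  if (min(gap) < 1.2 * h)
    stop(sprintf("under-resolved geometry: bowl-periderm gap %.4f mm < 1.2 cells",
                 min(gap)))

  inside_solid <- function(r, z) {
    # vectorised over r, z pairs
    below <- z <= He
    rper <- rp(z)
    rbowl <- rs_disp(z)
    incup <- z >= geometry$z_apex & z <= He & r < rbowl
    below & (r <= rper) & !incup
  }

  RC <- matrix(grid$r_centers, nr, nz)
  ZC <- matrix(grid$z_centers, nr, nz, byrow = TRUE)
  chi <- matrix(as.numeric(inside_solid(as.vector(RC), as.vector(ZC))), nr, nz)

  # face indicators: solid if either adjacent cell is solid
  chiR <- chi
  chiR[-nr, ] <- pmax(chi[-nr, ], chi[-1, ])
  chiZ <- chi
  chiZ[, -nz] <- pmax(chi[, -nz], chi[, -1])

  # prescribed face velocities (m/s); u_z = 0 on the whole surface
  usR <- matrix(0, nr, nz)
  if (!is.null(boundary)) {
    RF <- matrix(grid$r_faces, nr, nz)
    zc <- as.vector(ZC)
    rb <- rs_disp(zc)
    vs <- vsurf(zc)                                   # m/s at the wall
    wmv <- pmin(2 * h, (rp(zc) - rb) / 2)             # moving-layer half width
    moving <- as.vector(chiR) > 0 & zc >= geometry$z_apex & zc <= He &
      as.vector(RF) <= rb + wmv
    us <- vs * rb / pmax(as.vector(RF), h / 2)
    usR[matrix(moving, nr, nz)] <- us[moving]
  }
  usZ <- matrix(0, nr, nz)

  structure(list(grid = grid, geometry = geometry, boundary = boundary,
                 chi = chi, chi_rface = chiR, chi_zface = chiZ,
                 us_rface = usR, us_zface = usZ,
                 peak_speed = max(abs(usR))),
            class = "solid_mask")
}

#' @export
print.solid_mask <- function(x, ...) {
  cat(sprintf("solid mask: %d solid cells of %d; peak boundary speed %.3g m/s\n",
              sum(x$chi >= 0.5), length(x$chi), x$peak_speed))
  invisible(x)
}

#' Solid volume of a mask
#'
#' Volume of revolution represented by the solid cells, `sum(2 pi r_c h^2)`.
#' Converges to the analytic revolution volume of the profiles as the grid
#' is refined.
#'
#' @param mask A `solid_mask`.
#' @return Volume in mm^3.
#' @export
mask_solid_volume <- function(mask) {
  g <- mask$grid
  RC <- matrix(g$r_centers, g$nr, g$nz)
  sum(2 * pi * RC[mask$chi >= 0.5] * g$h^2)
}
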