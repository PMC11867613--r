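# Quasi-steady axisymmetric Stokes solver with volume penalization.
#
# At the scales simulated (mm body, ~1 s strokes) viscous forces dominate
# and the inertial terms of the Navier-Stokes equations are negligible, so
# each instant of the cycle is an independent stationary Stokes problem
# driven by the instantaneous boundary velocity:
#
#   0 = -grad p + mu Lap u - rho * chi/eta * (u - u_s),   div u = 0
#
# with chi the solid indicator and u_s the prescribed solid velocity
# (Brinkman volume penalization; eta is small so u -> u_s in the solid).
# Boundary conditions: axis symmetry at r = 0, no-slip floor at z = 0, open
# (traction-free, reference pressure 0) top and lateral boundaries.
#
# Discretely, the velocity problem is solved in symmetric positive definite
# form by grad-div augmentation: the momentum operator, weighted by cell
# volumes, is augmented with gamma * D' V D (D = discrete divergence over
# fluid cells) and the pressure is obtained as the augmented-Lagrangian
# multiplier via Uzawa iteration. Each iteration reuses one sparse Cholesky
# factorization, and the discrete divergence converges to round-off within a
# handful of iterations. Inside deeply solid cells the incompressibility
# constraint is not imposed (the tissue between the moving bowl wall and the
# rigid periderm is not a fluid region); the pressure is pinned to 0 there.

#' Fluid properties
#'
#' @param density Fluid density, kg/m^3 (default 1000, seawater-like).
#' @param viscosity Dynamic viscosity, Pa s (default 0.001).
#' @return An object of class `fluid_props`.
#' @export
fluid_props <- function(density = 1000, viscosity = 0.001) {
  if (density <= 0 || viscosity <= 0) stop("density and viscosity must be > 0")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_props")
}

#' Solver configuration
#'
#' @param eta Penalization time scale, s (smaller forces solid-cell
#'   velocities harder onto the prescribed values).
#' @param tol Relative tolerance on the discrete divergence, measured
#'   against `peak boundary speed / cell size`.
#' @param max_uzawa Maximum number of Uzawa pressure updates.
#' @param grad_div Dimensionless grad-div augmentation factor (multiplies
#'   the viscosity).
#' @param penal_error_max Largest admissible penalization error, as a
#'   fraction of the peak boundary speed.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(eta = 1e-8, tol = 1e-9, max_uzawa = 30,
                          grad_div = 1e4, penal_error_max = 0.01) {
  if (eta <= 0 || tol <= 0) stop("eta and tol must be > 0")
  structure(list(eta = eta, tol = tol, max_uzawa = max_uzawa,
                 grad_div = grad_div, penal_error_max = penal_error_max),
            class = "solver_config")
}

# Assemble the SPD augmented operator and divergence for a mask.
# Lengths enter in metres; returns operators plus index helpers.
assemble_stokes <- function(mask, props, cfg) {
  g <- mask$grid
  nr <- g$nr; nz <- g$nz
  h <- g$h * 1e-3                      # m
  mu <- props$viscosity
  rho <- props$density
  N <- nr * nz
  iur <- function(i, j) (j - 1) * nr + i
  iuz <- function(i, j) N + (j - 1) * nr + i

  rf <- g$r_faces * 1e-3               # radial face radii, m
  rc <- g$r_centers * 1e-3
  RFm <- matrix(rf, nr, nz)
  RCm <- matrix(rc, nr, nz)
  I <- rep(seq_len(nr), nz); J <- rep(seq_len(nz), each = nr)

  Ti <- vector("list", 24); Tj <- Ti; Tx <- Ti; kk <- 0
  push <- function(a, b, x) {
    kk <<- kk + 1; Ti[[kk]] <<- a; Tj[[kk]] <<- b; Tx[[kk]] <<- x
  }

  # u_r rows, volume weight r_f h^2
  sigR <- rho * mask$chi_rface / cfg$eta
  dg <- mu * (RFm + h / 2) + mu * (RFm - h / 2) + 2 * mu * RFm +
    mu * h^2 / RFm + RFm * h^2 * sigR
  dg[nr, ] <- dg[nr, ] - mu * (rf[nr] + h / 2)   # open side: drop outer flux
  dg[, 1]  <- dg[, 1]  + mu * RFm[, 1]           # no-slip floor (reflection)
  dg[, nz] <- dg[, nz] - mu * RFm[, nz]          # open top
  push(iur(I, J), iur(I, J), as.vector(dg))
  sel <- I < nr
  push(iur(I, J)[sel], iur(I + 1, J)[sel], as.vector(-mu * (RFm + h / 2))[sel])
  sel <- I > 1
  push(iur(I, J)[sel], iur(I - 1, J)[sel], as.vector(-mu * (RFm - h / 2))[sel])
  sel <- J < nz
  push(iur(I, J)[sel], iur(I, J + 1)[sel], as.vector(-mu * RFm)[sel])
  sel <- J > 1
  push(iur(I, J)[sel], iur(I, J - 1)[sel], as.vector(-mu * RFm)[sel])

  # u_z rows, volume weight r_c h^2
  sigZ <- rho * mask$chi_zface / cfg$eta
  rI <- matrix(rf, nr, nz)                       # column midradius i*h
  rIm1 <- matrix(c(0, rf[-nr]), nr, nz)          # (i-1)*h
  dg <- mu * (rI + rIm1) + 2 * mu * RCm + RCm * h^2 * sigZ
  dg[nr, ] <- dg[nr, ] - mu * rI[nr, ]
  dg[, nz] <- dg[, nz] - mu * RCm[, nz]
  push(iuz(I, J), iuz(I, J), as.vector(dg))
  sel <- I < nr
  push(iuz(I, J)[sel], iuz(I + 1, J)[sel], as.vector(-mu * rI)[sel])
  sel <- I > 1
  push(iuz(I, J)[sel], iuz(I - 1, J)[sel], as.vector(-mu * rIm1)[sel])
  sel <- J < nz
  push(iuz(I, J)[sel], iuz(I, J + 1)[sel], as.vector(-mu * RCm)[sel])
  sel <- J > 1
  push(iuz(I, J)[sel], iuz(I, J - 1)[sel], as.vector(-mu * RCm)[sel])

  K <- Matrix::sparseMatrix(i = unlist(Ti), j = unlist(Tj), x = unlist(Tx),
                            dims = c(2 * N, 2 * N))

  # divergence rows over fluid cells
  fid <- which(as.vector(mask$chi) < 0.5)
  nF <- length(fid)
  ci <- ((fid - 1) %% nr) + 1
  cj <- ((fid - 1) %/% nr) + 1
  rcc <- rc[ci]
  rw <- (ci - 1) * h
  Di <- vector("list", 4); Dj <- Di; Dx <- Di; kk <- 0
  pushD <- function(a, b, x) {
    kk <<- kk + 1; Di[[kk]] <<- a; Dj[[kk]] <<- b; Dx[[kk]] <<- x
  }
  pushD(seq_len(nF), iur(ci, cj), rf[ci] / (rcc * h))
  sel <- ci > 1
  pushD(which(sel), iur(pmax(ci - 1, 1), cj)[sel], (-rw / (rcc * h))[sel])
  pushD(seq_len(nF), iuz(ci, cj), rep(1 / h, nF))
  sel <- cj > 1
  pushD(which(sel), iuz(ci, pmax(cj - 1, 1))[sel], rep(-1 / h, sum(sel)))
  D <- Matrix::sparseMatrix(i = unlist(Di), j = unlist(Dj), x = unlist(Dx),
                            dims = c(nF, 2 * N))
  DtV <- Matrix::t(D) %*% Matrix::Diagonal(nF, rcc * h^2)

  f <- c(as.vector(RFm * h^2 * sigR * mask$us_rface),
         as.vector(RCm * h^2 * sigZ * mask$us_zface))

  list(K = K, D = D, DtV = DtV, f = f, fid = fid, nF = nF,
       nr = nr, nz = nz, N = N, h = h)
}

#' Solve the quasi-steady Stokes problem for one boundary state
#'
#' @param mask A `solid_mask` from [rasterize_solid()] (carries the grid and
#'   the embedded boundary velocities).
#' @param props A `fluid_props` object.
#' @param cfg A `solver_config` object.
#' @param time Time stamp to attach to the field, s.
#' @return An object of class `flow_field`: matrices `u_r`, `u_z` (m/s, on
#'   the staggered faces), `p` (Pa, cell centres), the grid, the cell
#'   indicator `chi`, and diagnostics `div_max` (1/s), `penal_error`
#'   (relative), `uzawa_iters`.
#' @export
solve_quasi_steady <- function(mask, props = fluid_props(),
                               cfg = solver_config(), time = 0) {
  stopifnot(inherits(mask, "solid_mask"))
  op <- assemble_stokes(mask, props, cfg)
  gam <- cfg$grad_div * props$viscosity
  Kg <- op$K + gam * (op$DtV %*% op$D)
  Ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kg), LDL = FALSE, super = TRUE)

  peak <- mask$peak_speed
  tol_abs <- cfg$tol * max(peak, 1e-30) / op$h
  lam <- numeric(op$nF)
  u <- numeric(2 * op$N)
  div_max <- Inf; it <- 0
  while (it < cfg$max_uzawa) {
    it <- it + 1
    u <- as.numeric(Matrix::solve(Ch, op$f - op$DtV %*% lam))
    du <- as.numeric(op$D %*% u)
    lam <- lam + gam * du
    div_max <- max(abs(du), 0)
    if (div_max <= tol_abs) break
  }
  if (div_max > tol_abs)
    stop(sprintf("Stokes solve did not converge: max|div| = %.3g after %d iterations",
                 div_max, it))

  nr <- op$nr; nz <- op$nz; N <- op$N
  ur <- matrix(u[seq_len(N)], nr, nz)
  uz <- matrix(u[N + seq_len(N)], nr, nz)
  p <- matrix(0, nr, nz)
  p[op$fid] <- -lam

  penal_error <- 0
  if (peak > 0) {
    selR <- mask$chi_rface > 0
    selZ <- mask$chi_zface > 0
    penal_error <- max(abs(ur - mask$us_rface)[selR],
                       abs(uz - mask$us_zface)[selZ], 0) / peak
    if (penal_error > cfg$penal_error_max)
      stop(sprintf("penalization error %.3g exceeds threshold %.3g",
                   penal_error, cfg$penal_error_max))
  }

  structure(list(time = time, u_r = ur, u_z = uz, p = p,
                 grid = mask$grid, chi = mask$chi,
                 div_max = div_max, penal_error = penal_error,
                 uzawa_iters = it),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "flow field at t = %.3f s: max speed %.3g m/s, max|div| %.3g 1/s (%d Uzawa iters)\n",
    x$time, max(abs(x$u_r), abs(x$u_z)), x$div_max, x$uzawa_iters))
  invisible(x)
}

#' Scale a flow field by a constant (Stokes linearity)
#' @noRd
scale_field <- function(field, k) {
  field$u_r <- field$u_r * k
  field$u_z <- field$u_z * k
  field$p <- field$p * k
  field
}

#' Volumetric flux through the aperture plane
#'
#' Signed integral of the axial velocity over the disc of aperture radius in
#' the first face plane above the peridermal aperture; positive means
#' outflow. During expansion this balances the cavity volume gain of the
#' bowl (influx), during contraction the expelled volume.
#'
#' @param field A `flow_field`.
#' @param geometry The `polyp_geometry` the field was computed around.
#' @return Volumetric rate in mm^3/s.
#' @export
aperture_flux <- function(field, geometry) {
  g <- field$grid
  j0 <- min(which(g$z_faces >= geometry$exposed_height))
  sel <- g$r_centers <= geometry$params$aperture_radius
  # u m/s -> mm/s; annulus areas in mm^2
  sum(field$u_z[sel, j0] * 1e3 * 2 * pi * g$r_centers[sel] * g$h)
}

#' Analytic radially expanding sphere (solver oracle)
#'
#' The creeping-flow field of a sphere of radius `a` whose surface expands
#' radially at rate `adot` is the point-source field `u_r = adot (a/r)^2`.
#' Used as an independent closed-form check on the penalized solver.
#'
#' @param a Sphere radius, mm.
#' @param adot Surface expansion speed, m/s.
#' @param radii Radial distances from the centre, mm (all >= a).
#' @return Radial speeds, m/s.
#' @export
analytic_expanding_sphere <- function(a, adot, radii) {
  if (a <= 0) stop("sphere radius must be > 0")
  if (any(radii < a)) stop("evaluation radii must be >= a")
  adot * (a / radii)^2
}
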