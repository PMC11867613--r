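# Solver oracles. The expensive checks run on the reduced-domain grid
# (identical cell size to the default); the expanding-sphere oracle uses a
# purpose-built spherical mask far from the boundaries.

sphere_mask <- function(grid, z0 = 2.5, a = 0.35, adot = 0.01) {
  geom <- build_polyp_profile(canonical_params())
  m <- rasterize_solid(geom, NULL, grid)    # container for mask fields
  RC <- matrix(grid$r_centers, grid$nr, grid$nz)
  ZC <- matrix(grid$z_centers, grid$nr, grid$nz, byrow = TRUE)
  chi <- (RC^2 + (ZC - z0)^2 < a^2) * 1
  chiR <- chi; chiR[-grid$nr, ] <- pmax(chi[-grid$nr, ], chi[-1, ])
  chiZ <- chi; chiZ[, -grid$nz] <- pmax(chi[, -grid$nz], chi[, -1])
  RF <- matrix(grid$r_faces, grid$nr, grid$nz)
  ZF <- matrix(grid$z_faces, grid$nr, grid$nz, byrow = TRUE)
  dR <- sqrt(RF^2 + (ZC - z0)^2)
  dZ <- sqrt(RC^2 + (ZF - z0)^2)
  m$chi <- chi; m$chi_rface <- chiR; m$chi_zface <- chiZ
  m$us_rface <- ifelse(chiR > 0, adot * RF / pmax(dR, grid$h / 2), 0)
  m$us_zface <- ifelse(chiZ > 0, adot * (ZF - z0) / pmax(dZ, grid$h / 2), 0)
  m$peak_speed <- adot
  m
}

test_that("zero boundary motion yields the hydrostatic rest state", {
  g <- canonical_geometry()
  mask <- rasterize_solid(g, NULL, small_grid())
  f <- solve_quasi_steady(mask, time = 0)
  expect_equal(max(abs(f$u_r), abs(f$u_z)), 0)
})

test_that("the expanding-sphere field matches the analytic source solution", {
  grid <- small_grid()
  a <- 0.35; adot <- 0.01
  mask <- sphere_mask(grid, z0 = 2.5, a = a, adot = adot)
  f <- solve_quasi_steady(mask)
  # sample at 2a above, below, and beside the centre
  expect_equal(analytic_expanding_sphere(a, adot, 2 * a), adot / 4)
  v_top <- field_velocity_at(f, 0, 2.5 + 2 * a)
  v_side <- field_velocity_at(f, 2 * a, 2.5)
  expect_equal(abs(v_top$u_z), adot / 4, tolerance = 0.1)
  expect_equal(abs(v_side$u_r), adot / 4, tolerance = 0.1)
  # and the oracle itself: r = a gives adot; r < a rejected
  expect_equal(analytic_expanding_sphere(a, adot, a), adot)
  expect_error(analytic_expanding_sphere(a, adot, 0.5 * a), ">= a")
  # numerically divergence-free outside the sphere: d(r^2 u)/dr = 0
  rr <- seq(1.2 * a, 3 * a, length.out = 50)
  u <- analytic_expanding_sphere(a, adot, rr)
  flux <- rr^2 * u
  expect_lt(max(abs(diff(flux))) / flux[1], 1e-12)
})

test_that("solutions are linear and reversible in the boundary data", {
  s <- small_snapshot()
  f1 <- s$field
  mask2 <- s$mask
  mask2$us_rface <- 2 * mask2$us_rface
  mask2$us_zface <- 2 * mask2$us_zface
  mask2$peak_speed <- 2 * mask2$peak_speed
  f2 <- solve_quasi_steady(mask2, s$cfg$fluid, s$cfg$solver)
  expect_lt(max(abs(f2$u_r - 2 * f1$u_r)) / max(abs(f1$u_r)), 1e-10)
  expect_lt(max(abs(f2$u_z - 2 * f1$u_z)) / max(abs(f1$u_z)), 1e-10)

  maskn <- s$mask
  maskn$us_rface <- -maskn$us_rface
  maskn$us_zface <- -maskn$us_zface
  fn <- solve_quasi_steady(maskn, s$cfg$fluid, s$cfg$solver)
  expect_identical(fn$u_r, -f1$u_r)     # kinematic reversibility, bitwise
  expect_identical(fn$u_z, -f1$u_z)
})

test_that("discrete divergence and penalization error meet their bounds", {
  s <- small_snapshot()
  f <- s$field
  g <- f$grid; h <- g$h * 1e-3
  expect_lt(f$div_max, s$cfg$solver$tol * s$mask$peak_speed / h)
  expect_lt(f$penal_error, s$cfg$solver$penal_error_max)
  # recompute the divergence independently from the stored field
  nr <- g$nr; nz <- g$nz
  urf <- rbind(0, f$u_r); uzf <- cbind(0, f$u_z)
  rf <- c(0, g$r_faces) * 1e-3; rc <- g$r_centers * 1e-3
  div <- matrix(0, nr, nz)
  for (i in seq_len(nr))
    div[i, ] <- (rf[i + 1] * urf[i + 1, ] - rf[i] * urf[i, ]) / (rc[i] * h) +
      (uzf[i, -1] - uzf[i, -(nz + 1)]) / h
  expect_lt(max(abs(div[f$chi < 0.5])), 1e-6 * s$mask$peak_speed / h)
})

test_that("quasi-steadiness: a snapshot recomputed in isolation is identical", {
  s <- small_snapshot()
  f2 <- solve_quasi_steady(rasterize_solid(s$geometry, s$boundary, s$cfg$grid),
                           s$cfg$fluid, s$cfg$solver, time = 0.6)
  expect_identical(f2$u_r, s$field$u_r)
  expect_identical(f2$u_z, s$field$u_z)
})

test_that("aperture flux reproduces closed forms and the volume-rate oracle", {
  s <- small_snapshot()
  g <- s$geometry
  zero <- s$field; zero$u_z[] <- 0; zero$u_r[] <- 0
  expect_equal(aperture_flux(zero, g), 0)
  # uniform axial speed w over the aperture disc
  w <- 0.01
  uni <- zero; uni$u_z[] <- w
  a_r <- g$params$aperture_radius
  sel <- s$cfg$grid$r_centers <= a_r
  disc_area <- sum(2 * pi * s$cfg$grid$r_centers[sel] * s$cfg$grid$h)
  expect_equal(aperture_flux(uni, g), w * 1e3 * disc_area)
  expect_equal(disc_area, pi * a_r^2, tolerance = 0.15)  # stair-step disc
  # mid-expansion: flux into the cavity balances the analytic volume rate
  flux <- aperture_flux(s$field, g)
  dVdt <- polypflow:::cavity_volume_rate(g, s$cfg$motion, 0.6)
  expect_equal(-flux, dVdt, tolerance = 0.05)
})

test_that("mass is conserved across a control surface around the rigid floor", {
  # net flux through a box enclosing only rigid geometry (no moving wall):
  # integrate the velocity over the closed surface r = r0, z in [0, z0]
  # plus the lid z = z0, r <= r0 (floor contributes zero by no-slip)
  s <- small_snapshot()
  f <- s$field; g <- f$grid
  r0i <- 55; z0j <- 110       # box enclosing the whole polyp
  lid <- sum(f$u_z[seq_len(r0i), z0j] * 2 * pi * g$r_centers[seq_len(r0i)] * g$h)
  side <- sum(f$u_r[r0i, seq_len(z0j)] * 2 * pi * g$r_faces[r0i] * g$h)
  net <- lid + side                         # m/s * mm^2
  scale <- max(abs(f$u_z)) * pi * g$r_faces[r0i]^2
  # the box contains the pumping bowl: net flux equals the cavity fill rate
  dVdt <- polypflow:::cavity_volume_rate(s$geometry, s$cfg$motion, 0.6)
  expect_equal(-(net * 1e3), dVdt, tolerance = 0.05)
  # a smaller box in the far field away from the polyp encloses nothing
  r1i <- 50
  lid1 <- sum(f$u_z[seq_len(r1i), 100] * 2 * pi * g$r_centers[seq_len(r1i)] * g$h)
  lid2 <- sum(f$u_z[seq_len(r1i), 60] * 2 * pi * g$r_centers[seq_len(r1i)] * g$h)
  side1 <- sum(f$u_r[r1i, 61:100] * 2 * pi * g$r_faces[r1i] * g$h)
  expect_lt(abs(lid1 - lid2 + side1) / max(abs(lid1), scale * 1e-8), 1e-6)
})
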