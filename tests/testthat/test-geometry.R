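test_that("canonical parameters carry the fossil-derived dimensions", {
  p <- canonical_params()
  expect_equal(p$periderm_height, 2.0)
  expect_equal(p$periderm_base_radius, 0.3)
  expect_equal(p$insertion_depth, 0.18)
  expect_equal(p$subumbrella_height, 0.7)
})

test_that("parameter validation rejects inconsistent shapes", {
  expect_error(geometry_params(aperture_radius = 0.4), "aperture_radius")
  expect_error(geometry_params(insertion_depth = 2.5), "insertion_depth")
  expect_error(geometry_params(periderm_height = -1), "lengths")
  expect_error(geometry_params(opening_radius = 0.2), "opening_radius")
})

test_that("exposed height identity holds for random valid parameter draws", {
  set.seed(42)
  for (k in 1:25) {
    ph <- runif(1, 1, 3)
    ins <- runif(1, 0, 0.4 * ph)
    p <- geometry_params(periderm_height = ph, insertion_depth = ins,
                         subumbrella_height = 0.3 * ph)
    g <- build_polyp_profile(p)
    expect_equal(g$exposed_height, ph - ins)
  }
})

test_that("profiles honour the printed dimensions and attachment", {
  g <- canonical_geometry()
  expect_equal(g$exposed_height, 1.82)
  zz <- seq(0, g$exposed_height, length.out = 500)
  expect_equal(max(g$periderm_profile(zz)), 0.3)       # base radius
  # bowl rim attaches at the aperture level with the configured opening
  expect_equal(g$subumbrella_profile(g$z_rim), g$params$opening_radius)
  expect_equal(g$subumbrella_profile(g$z_apex), 0)
  # profiles single-valued and non-negative
  zb <- seq(g$z_apex, g$z_rim, length.out = 500)
  expect_true(all(g$subumbrella_profile(zb) >= 0))
  expect_true(all(g$periderm_profile(zz) > 0))
  # zero insertion exposes the full height
  g0 <- build_polyp_profile(geometry_params(insertion_depth = 0))
  expect_equal(g0$exposed_height, 2.0)
})

test_that("bowl-periderm intersection is rejected", {
  expect_error(build_polyp_profile(
    geometry_params(subumbrella_max_radius = 0.19, opening_radius = 0.05,
                    aperture_radius = 0.1)),
    "periderm")
})

test_that("cavity volume matches closed forms", {
  g <- canonical_geometry()
  # bounded by the circumscribing cylinder of the bowl
  expect_gt(g$rest_cavity_volume, 0)
  expect_lt(g$rest_cavity_volume,
            pi * g$params$subumbrella_max_radius^2 * g$params$subumbrella_height)

  # near-cylindrical bowl: analytic pi R^2 h, first-order wall displacement
  cyl <- build_polyp_profile(geometry_params(
    subumbrella_max_radius = 0.1, opening_radius = 0.0999,
    belly_fraction = 0.01, aperture_radius = 0.25, taper_exponent = 1))
  h_bowl <- cyl$params$subumbrella_height
  # profile is R almost everywhere except a tiny apex cap
  expect_equal(cyl$rest_cavity_volume, pi * 0.1^2 * h_bowl, tolerance = 0.02)
  dl <- 1e-4
  dV <- cavity_volume(cyl, function(z) rep(dl, length(z))) - cyl$rest_cavity_volume
  expect_equal(dV, 2 * pi * 0.1 * h_bowl * dl, tolerance = 0.03)

  # self-intersecting displacement rejected
  expect_error(cavity_volume(g, function(z) rep(-1, length(z))),
               "self-intersecting")
})

test_that("rasterization marks far field as fluid and converges in volume", {
  g <- canonical_geometry()
  grid <- small_grid()
  m <- rasterize_solid(g, NULL, grid)
  # far-field cell is fluid
  ci <- which.min(abs(grid$r_centers - 2)); cj <- which.min(abs(grid$z_centers - 4))
  expect_equal(m$chi[ci, cj], 0)
  # zero-motion mask carries zero velocities
  expect_true(all(m$us_rface == 0) && all(m$us_zface == 0))
  expect_equal(m$peak_speed, 0)

  # analytic solid revolution volume: periderm body minus bowl cavity
  zz <- seq(0, g$exposed_height, length.out = 4001)
  hstep <- zz[2] - zz[1]
  vol_body <- pi * sum(g$periderm_profile(zz)^2) * hstep
  vol_solid <- vol_body - g$rest_cavity_volume
  errs <- sapply(c(75, 150, 300), function(n) {   # 3-level halving ladder
    gr <- domain_grid(2.5, 5, n, 2 * n)
    abs(mask_solid_volume(rasterize_solid(g, NULL, gr)) - vol_solid)
  })
  expect_true(all(diff(errs) < 0))           # monotone decreasing error
  expect_lt(errs[3] / vol_solid, 0.01)
})

test_that("under-resolved geometries are signalled", {
  g <- canonical_geometry()
  coarse <- domain_grid(5, 10, 40, 80)       # h = 0.125 mm > rim opening
  expect_error(rasterize_solid(g, NULL, coarse), "under-resolved")
})

test_that("profile tables export the expected columns", {
  g <- canonical_geometry()
  for (w in c("periderm", "subumbrella")) {
    df <- profile_table(g, w)
    expect_named(df, c("z_mm", "r_mm"))
    expect_true(all(df$r_mm >= 0))
  }
})
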