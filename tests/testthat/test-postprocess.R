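test_that("max velocity table reduces traces correctly", {
  res <- memo("run_small_11", run_scenario(small_config(), store_fields = TRUE))
  # synthetic constant trace: maximum equals the constant
  fake <- res
  fake$traces[] <- 3.14e-4
  tab <- max_velocity_table(list(fake), phase = "full", refine_dt = NULL)
  expect_true(all(tab[["1:1"]] == 3.14e-4))
  # real run: maxima decay away from the aperture
  tab <- max_velocity_table(list(res), phase = "expansion", refine_dt = NULL)
  expect_gt(tab[["1:1"]][1], tab[["1:1"]][10])
  expect_true(all(diff(tab[["1:1"]]) <= 0))
})

test_that("vorticity obeys its closed forms", {
  res <- memo("run_small_11", run_scenario(small_config(), store_fields = TRUE))
  f <- res$fields[[4]]
  g <- f$grid
  # uniform field: omega = 0
  uni <- f; uni$u_r[] <- 0.003; uni$u_z[] <- -0.001
  w <- vorticity(uni)
  expect_lt(max(abs(w$omega[2:(g$nr - 1), 2:(g$nz - 1)])), 1e-12)
  # pure shear u_r = c z: omega = c in the interior
  c0 <- 2.5
  sh <- f; sh$u_z[] <- 0
  sh$u_r <- matrix(rep(c0 * g$z_centers * 1e-3, each = g$nr), g$nr, g$nz)
  w <- vorticity(sh)
  expect_equal(max(abs(w$omega[2:(g$nr - 1), 3:(g$nz - 2)] - c0)), 0,
               tolerance = 1e-9)
  # odd under field negation, bitwise
  neg <- f; neg$u_r <- -f$u_r; neg$u_z <- -f$u_z
  expect_identical(vorticity(neg)$omega, -vorticity(f)$omega)
  # nondimensional copy scales with T_scale
  expect_identical(vorticity(f, T_scale = 2)$omega_star, 2 * vorticity(f)$omega)
})

test_that("reynolds number is the exact ratio formula", {
  expect_equal(reynolds_number(1000, 0.01, 1e-4, 0.001), 1)
  expect_equal(reynolds_number(1000, 0, 1e-4, 0.001), 0)
  expect_equal(reynolds_number(500, 0.02, 2e-4, 0.002), 1)
  # linear in each numerator argument, inverse in viscosity
  base <- reynolds_number(800, 0.004, 3e-4, 0.0015)
  expect_equal(reynolds_number(1600, 0.004, 3e-4, 0.0015), 2 * base)
  expect_equal(reynolds_number(800, 0.008, 3e-4, 0.0015), 2 * base)
  expect_equal(reynolds_number(800, 0.004, 6e-4, 0.0015), 2 * base)
  expect_equal(reynolds_number(800, 0.004, 3e-4, 0.003), base / 2)
  expect_error(reynolds_number(1000, 0.01, 1e-4, 0), "viscosity")
})

test_that("component labelling separates disjoint blobs", {
  B <- matrix(FALSE, 10, 12)
  B[2:3, 2:3] <- TRUE
  B[7:9, 8:10] <- TRUE
  B[5, 12] <- TRUE
  lb <- polypflow:::label_components(B)
  expect_equal(lb$n, 3)
  expect_equal(sort(unique(as.vector(lb$labels))), 0:3)
  expect_length(unique(lb$labels[B]), 3)
})

test_that("a translating synthetic blob separates at the constructed frame", {
  res <- memo("run_small_11", run_scenario(small_config(), store_fields = TRUE))
  g <- res$fields[[1]]$grid
  geom <- res$geometry
  RC <- matrix(g$r_centers, g$nr, g$nz)
  ZC <- matrix(g$z_centers, g$nr, g$nz, byrow = TRUE)
  mk <- function(r0, z0) {
    f <- res$fields[[1]]
    v <- vorticity(f)
    v$omega_star <- exp(-(((RC - r0)^2 + (ZC - z0)^2) / 0.02)) * 1e-2
    v
  }
  # blob starts adjacent to the flank, then jumps clear of it
  He <- geom$exposed_height
  r_ap <- geom$params$aperture_radius
  frames <- list(mk(r_ap + 0.02, He - 0.1), mk(r_ap + 0.1, He - 0.1),
                 mk(r_ap + 0.35, He + 0.2), mk(r_ap + 0.45, He + 0.4))
  frames[[1]]$time <- 0.1; frames[[2]]$time <- 0.2
  frames[[3]]$time <- 0.3; frames[[4]]$time <- 0.4
  tk <- track_vortices(frames, geom, T_exp = 1, threshold = 1e-3,
                       delta = 0.15, link_dist = 1.0)
  sep <- subset(tk$events, structure == "main" & event == "separation")
  expect_equal(sep$time_s, 0.3)
})

test_that("two identical grids give zero sensitivity difference", {
  cfg <- small_config()
  cfg$snapshot_interval <- 0.25
  rep <- grid_sensitivity(cfg, levels = 2, ratio = "1:1", factor = 1)
  expect_equal(rep$pairs$avg_rel_diff_pct, 0)
  expect_error(grid_sensitivity(cfg, levels = 1), "two grid levels")
})

test_that("successive refinement differences shrink on a three-level ladder", {
  cfg <- small_config()
  cfg$snapshot_interval <- 0.2
  rep <- grid_sensitivity(cfg, levels = 3, ratio = "1:1", factor = sqrt(2))
  d <- rep$pairs$avg_rel_diff_pct
  expect_length(d, 2)
  expect_true(all(d >= 0))
  expect_lt(d[2], d[1])
})

test_that("flat CSV field export carries the staggered field to cell centres", {
  res <- memo("run_small_11", run_scenario(small_config(), store_fields = TRUE))
  p <- file.path(tempdir(), "field.csv")
  write_field_csv(res$fields[[4]], p)
  df <- read.csv(p)
  expect_named(df, c("r_mm", "z_mm", "u_r", "u_z", "p"))
  expect_equal(nrow(df), res$config$grid$nr * res$config$grid$nz)
  expect_equal(max(abs(df$u_z)), max(abs(res$fields[[4]]$u_z)), tolerance = 0.2)
  unlink(p)
})
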