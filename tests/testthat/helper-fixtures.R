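# Shared fixtures. Heavy canonical runs are computed once per test session
# and memoised in this environment; tests that only need cheap objects use
# the small grid below.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# reduced domain for fast physics tests (same 41.7 um cells, half extents)
small_grid <- function() domain_grid(radius_extent = 2.5, height_extent = 5,
                                     nr = 60, nz = 120)

small_config <- function(T_exp = 1, T_con = 1, ...) {
  scenario_config(motion = motion_spec(T_exp = T_exp, T_con = T_con, ...),
                  grid = small_grid(),
                  snapshot_interval = 0.1)
}

canonical_geometry <- function() memo("geom", build_polyp_profile(canonical_params()))

# full default-grid sweep over the four canonical ratios (shared by the
# acceptance tests; several minutes of compute)
canonical_sweep <- function() memo("sweep", {
  cfg <- scenario_config()
  run_sweep(c("1:1", "2:1", "3:1", "4:1"), cfg, store_fields = FALSE)
})

# default-grid 3:1 run with stored fields (vortex chronology, timing)
canonical_run31 <- function() memo("run31", {
  run_scenario(scenario_config(), ratio = "3:1", store_fields = TRUE)
})

# one mid-expansion snapshot on the small grid
small_snapshot <- function() memo("snap", {
  cfg <- small_config()
  g <- build_polyp_profile(cfg$geometry)
  b <- displaced_surface(g, cfg$motion, 0.6)
  m <- rasterize_solid(g, b, cfg$grid)
  list(cfg = cfg, geometry = g, boundary = b, mask = m,
       field = solve_quasi_steady(m, cfg$fluid, cfg$solver, time = 0.6))
})
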