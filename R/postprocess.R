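# Derived quantities: per-point velocity maxima, vorticity and vortex-core
# chronology, Reynolds number, and grid-sensitivity reports.

phase_window <- function(result, phase) {
  Te <- result$config$motion$T_exp
  Tc <- result$config$motion$T_cycle
  switch(phase,
         expansion = c(0, Te),
         contraction = c(Te, Tc),
         full = c(0, Tc),
         stop("phase must be 'expansion', 'contraction' or 'full'"))
}

#' Locate the peak speed of a trace within a phase
#'
#' Finds the snapshot-time maximum of the speed at one cut point and, if
#' requested, refines the peak location with additional solves at a finer
#' time step around it.
#'
#' @param result A `simulation_result`.
#' @param phase `"expansion"`, `"contraction"` or `"full"`.
#' @param point Index of the cut point (default 1, the station nearest the
#'   aperture).
#' @param refine_dt Fine time step, s; `NULL` skips refinement.
#' @return List with `time` (s) and `speed` (m/s) of the peak.
#' @export
find_phase_peak <- function(result, phase = "expansion", point = 1,
                            refine_dt = 0.01) {
  win <- phase_window(result, phase)
  sel <- which(result$times >= win[1] & result$times <= win[2])
  tr <- result$traces[sel, point]
  k <- sel[which.max(tr)]
  t0 <- result$times[k]
  best <- list(time = t0, speed = result$traces[k, point])
  if (!is.null(refine_dt)) {
    dt0 <- result$config$snapshot_interval
    tt <- seq(max(win[1], t0 - dt0), min(win[2], t0 + dt0), by = refine_dt)
    tt <- setdiff(round(tt, 9), round(result$times, 9))
    if (length(tt)) {
      sp <- snapshot_speeds(result$config, tt)[, point]
      if (max(sp) > best$speed)
        best <- list(time = tt[which.max(sp)], speed = max(sp))
    }
  }
  best
}

#' Table of per-point maximum speeds across scenarios
#'
#' For every cut point and every scenario, the maximum sampled speed over
#' the requested phase. Peak times are refined with finer sampling around
#' the coarse maximum of the aperture-adjacent point (all points share the
#' extra sample times).
#'
#' @param results List of `simulation_result` sharing the cut-point spec.
#' @param phase `"expansion"`, `"contraction"` or `"full"`.
#' @param refine_dt Fine time step for peak refinement, s; `NULL` to skip.
#' @return A data.frame: `z_mm` column plus one column of maxima (m/s) per
#'   scenario label; the phase is attached as attribute `"phase"`.
#' @export
max_velocity_table <- function(results, phase = "expansion",
                               refine_dt = 0.01) {
  if (inherits(results, "simulation_result")) results <- list(results)
  zp <- results[[1]]$config$cut_points$z
  out <- data.frame(z_mm = zp)
  for (res in results) {
    if (!isTRUE(all.equal(res$config$cut_points$z, zp)))
      stop("results do not share the cut-point specification")
    win <- phase_window(res, phase)
    sel <- which(res$times >= win[1] & res$times <= win[2])
    mx <- apply(res$traces[sel, , drop = FALSE], 2, max)
    if (!is.null(refine_dt)) {
      k <- sel[which.max(res$traces[sel, 1])]
      t0 <- res$times[k]
      dt0 <- res$config$snapshot_interval
      tt <- seq(max(win[1], t0 - dt0), min(win[2], t0 + dt0), by = refine_dt)
      tt <- setdiff(round(tt, 9), round(res$times, 9))
      if (length(tt)) mx <- pmax(mx, apply(snapshot_speeds(res$config, tt), 2, max))
    }
    out[[res$label]] <- unname(mx)
  }
  attr(out, "phase") <- phase
  out
}

#' Azimuthal vorticity of a flow field
#'
#' Centred finite-difference curl component
#' `omega_phi = d u_r / d z - d u_z / d r` evaluated at cell centres
#' (one-sided at the domain edges), with an optional nondimensional copy
#' `omega* = omega_phi * T_scale`.
#'
#' @param field A `flow_field`.
#' @param T_scale Time scale for nondimensionalization, s (default 1, the
#'   contraction duration of the canonical scenarios).
#' @return An object of class `vorticity_field` with matrices `omega`
#'   (1/s) and `omega_star` at cell centres.
#' @export
vorticity <- function(field, T_scale = 1) {
  g <- field$grid
  nr <- g$nr; nz <- g$nz
  h <- g$h * 1e-3                           # m
  # interpolate to cell centres
  urf <- rbind(0, field$u_r)                # axis face
  uc_r <- (urf[-(nr + 1), , drop = FALSE] + urf[-1, , drop = FALSE]) / 2
  uzf <- cbind(0, field$u_z)                # floor face
  uc_z <- (uzf[, -(nz + 1), drop = FALSE] + uzf[, -1, drop = FALSE]) / 2
  ddz <- function(m) {
    d <- m
    d[, 2:(nz - 1)] <- (m[, 3:nz] - m[, 1:(nz - 2)]) / (2 * h)
    d[, 1] <- (m[, 2] - m[, 1]) / h
    d[, nz] <- (m[, nz] - m[, nz - 1]) / h
    d
  }
  ddr <- function(m) {
    d <- m
    d[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / (2 * h)
    d[1, ] <- (m[2, ] - m[1, ]) / h
    d[nr, ] <- (m[nr, ] - m[nr - 1, ]) / h
    d
  }
  omega <- ddz(uc_r) - ddr(uc_z)
  structure(list(time = field$time, omega = omega,
                 omega_star = omega * T_scale, T_scale = T_scale,
                 grid = g, chi = field$chi),
            class = "vorticity_field")
}

#' Reynolds number
#'
#' `Re = rho U L / mu`, the ratio of inertial to viscous forces. Values
#' below 1 indicate the viscosity-dominated regime in which the
#' quasi-steady creeping-flow model applies.
#'
#' @param rho Density, kg/m^3. @param U Characteristic speed, m/s.
#' @param L Characteristic length, m. @param mu Dynamic viscosity, Pa s.
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(rho, U, L, mu) {
  if (mu <= 0) stop("viscosity must be > 0")
  if (any(c(rho, U, L) < 0)) stop("rho, U, L must be >= 0")
  rho * U * L / mu
}

# 4-connected component labelling of a logical matrix
label_components <- function(B) {
  lab <- matrix(0L, nrow(B), ncol(B))
  nlab <- 0L
  nr <- nrow(B)
  n <- length(B)
  for (start in which(B)) {
    if (lab[start] != 0L) next
    nlab <- nlab + 1L
    frontier <- start
    lab[start] <- nlab
    while (length(frontier)) {
      rows <- (frontier - 1L) %% nr
      nb <- c(frontier[rows > 0L] - 1L, frontier[rows < nr - 1L] + 1L,
              frontier - nr, frontier + nr)
      nb <- nb[nb >= 1L & nb <= n]
      nb <- unique(nb[B[nb] & lab[nb] == 0L])
      lab[nb] <- nlab
      frontier <- nb
    }
  }
  list(labels = lab, n = nlab)
}

# distance field (mm) from cell centres to the periderm flank surface
periderm_distance_field <- function(grid, geometry) {
  zz <- seq(0, geometry$exposed_height, length.out = 300)
  sr <- geometry$periderm_profile(zz)
  D <- matrix(0, grid$nr, grid$nz)
  for (j in seq_len(grid$nz))
    D[, j] <- sqrt(apply(outer(grid$r_centers, sr, "-")^2 +
                           outer(rep(grid$z_centers[j], grid$nr), zz, "-")^2,
                         1, min))
  D
}

#' Track vortex structures through a sequence of vorticity fields
#'
#' Detects, in every frame, the connected same-signed regions of the fluid
#' outside the periderm where `|omega*|` exceeds an absolute threshold (the
#' analogue of a saturated colour scale in a vorticity visualisation), takes
#' each region's extremum as its core, links regions frame-to-frame by core
#' proximity and sign, and emits the event chronology:
#'
#' * `formation` -- first frame the structure is detected;
#' * `floor_contact` -- its pixels first reach the domain floor
#'   (within `floor_dist`);
#' * `separation` -- the structure, having previously been in contact with
#'   the periderm flank (some pixel within `delta` of the surface), first
#'   retains no such contact: either its remaining pixels lie farther than
#'   `delta` from the flank, or it has faded below the detection threshold
#'   altogether. In quasi-steady creeping flow a stroke-driven structure
#'   fades in place as the stroke rate vanishes, so loss of wall contact by
#'   fading is the generic separation mode;
#' * `dissolution` -- first frame after the structure's last detection.
#'
#' The expansion-phase `main` structure is the strongest one formed near the
#' aperture during expansion; the `secondary` is the strongest
#' opposite-signed structure of the expansion phase; `main_contraction` is
#' the opposite-signed aperture structure that replaces the main at the
#' phase turnover.
#'
#' @param vfields List of `vorticity_field` in time order (at least 2).
#' @param geometry The `polyp_geometry` simulated around.
#' @param T_exp Expansion duration, s (phase boundary for classification).
#' @param threshold Absolute detection threshold on `|omega*|`. The default
#'   2e-4 (with the default `T_scale` of 1 s) detects both dominant
#'   opposite-signed structures of the canonical runs over their full
#'   spatial development, including the secondary structure's descent along
#'   the periderm to the floor.
#' @param delta Wall-contact distance to the periderm flank, mm; default two
#'   grid cells.
#' @param floor_dist Floor-contact distance, mm; default two grid cells.
#' @param link_dist Maximum core displacement between frames, mm.
#' @return An object of class `vortex_track`: per-frame core tables,
#'   per-track trajectories, the labelled structures, and an `events`
#'   data.frame (`structure`, `event`, `time_s`).
#' @export
track_vortices <- function(vfields, geometry, T_exp,
                           threshold = 2e-4, delta = NULL,
                           floor_dist = NULL, link_dist = 0.5) {
  if (length(vfields) < 2) stop("need at least two frames")
  g <- vfields[[1]]$grid
  if (is.null(delta)) delta <- 2 * g$h
  if (is.null(floor_dist)) floor_dist <- 2 * g$h
  RC <- matrix(g$r_centers, g$nr, g$nz)
  ZC <- matrix(g$z_centers, g$nr, g$nz, byrow = TRUE)
  He <- geometry$exposed_height
  exterior <- !(ZC <= He & RC <= geometry$periderm_profile(as.vector(ZC))) &
    vfields[[1]]$chi < 0.5
  DST <- periderm_distance_field(g, geometry)

  frames <- list()
  tracks <- list()   # id, sign, times, r, z, peak, min_z, wall_dist, last_seen
  active <- integer(0)
  any_detect <- FALSE
  for (f in seq_along(vfields)) {
    vf <- vfields[[f]]
    W <- vf$omega_star
    W[!exterior] <- 0
    cores <- NULL
    for (sgn in c(1, -1)) {
      B <- (sgn * W) >= threshold
      if (!any(B)) next
      any_detect <- TRUE
      lb <- label_components(B)
      cc <- do.call(rbind, lapply(seq_len(lb$n), function(l) {
        idx <- which(lb$labels == l)
        core <- idx[which.max(abs(W[idx]))]
        data.frame(r = RC[core], z = ZC[core], sign = sgn,
                   peak = abs(W[core]), min_z = min(ZC[idx]),
                   wall_dist = min(DST[idx]), size = length(idx))
      }))
      cores <- rbind(cores, cc)
    }
    frames[[f]] <- cores

    newactive <- integer(0)
    if (!is.null(cores)) {
      used <- rep(FALSE, nrow(cores))
      for (id in active) {
        tr <- tracks[[id]]
        last_r <- tr$r[length(tr$r)]; last_z <- tr$z[length(tr$z)]
        d <- sqrt((cores$r - last_r)^2 + (cores$z - last_z)^2)
        d[used | cores$sign != tr$sign] <- Inf
        if (any(is.finite(d)) && min(d) <= link_dist) {
          j <- which.min(d)
          used[j] <- TRUE
          tr$times <- c(tr$times, vf$time)
          tr$r <- c(tr$r, cores$r[j]); tr$z <- c(tr$z, cores$z[j])
          tr$peak <- c(tr$peak, cores$peak[j])
          tr$min_z <- c(tr$min_z, cores$min_z[j])
          tr$wall_dist <- c(tr$wall_dist, cores$wall_dist[j])
          tracks[[id]] <- tr
          newactive <- c(newactive, id)
        } else {
          tracks[[id]]$died_at <- vf$time
        }
      }
      for (j in which(!used)) {
        id <- length(tracks) + 1L
        tracks[[id]] <- list(id = id, sign = cores$sign[j],
                             times = vf$time, r = cores$r[j], z = cores$z[j],
                             peak = cores$peak[j], min_z = cores$min_z[j],
                             wall_dist = cores$wall_dist[j], died_at = NA)
        newactive <- c(newactive, id)
      }
    } else {
      for (id in active)
        if (is.na(tracks[[id]]$died_at)) tracks[[id]]$died_at <- vf$time
    }
    active <- newactive
  }
  if (!any_detect) stop("no vorticity above threshold in any frame")

  rim_pt <- c(geometry$params$aperture_radius, He)
  near_ap <- vapply(tracks, function(tr)
    sqrt((tr$r[1] - rim_pt[1])^2 + (tr$z[1] - rim_pt[2])^2) < 0.6, logical(1))
  formed_exp <- vapply(tracks, function(tr) tr$times[1] < T_exp, logical(1))
  signs <- vapply(tracks, function(tr) tr$sign, numeric(1))
  peaks <- vapply(tracks, function(tr) max(tr$peak), numeric(1))

  pick <- function(sel) if (any(sel)) which(sel)[which.max(peaks[sel])] else NA_integer_
  main_id <- pick(formed_exp & near_ap)
  sec_id <- if (is.na(main_id)) NA_integer_ else
    pick(formed_exp & signs == -tracks[[main_id]]$sign &
           seq_along(tracks) != main_id)
  turn_id <- if (is.na(main_id)) NA_integer_ else
    pick(vapply(tracks, function(tr) tr$times[1], numeric(1)) >= T_exp - 0.1 &
           signs == -tracks[[main_id]]$sign & near_ap)

  events <- data.frame(structure = character(0), event = character(0),
                       time_s = numeric(0))
  add_event <- function(structure, event, time)
    events <<- rbind(events, data.frame(structure = structure, event = event,
                                        time_s = time))
  track_events <- function(id, name) {
    tr <- tracks[[id]]
    add_event(name, "formation", tr$times[1])
    fc <- which(tr$min_z <= floor_dist)
    if (length(fc)) add_event(name, "floor_contact", tr$times[fc[1]])
    # separation: loss of wall contact after having had it
    contact <- tr$wall_dist <= delta
    if (any(contact)) {
      first_c <- which(contact)[1]
      lost <- which(!contact & seq_along(contact) > first_c)
      if (length(lost)) add_event(name, "separation", tr$times[lost[1]])
      else if (!is.na(tr$died_at)) add_event(name, "separation", tr$died_at)
    }
    if (!is.na(tr$died_at)) add_event(name, "dissolution", tr$died_at)
  }
  if (!is.na(main_id)) track_events(main_id, "main")
  if (!is.na(sec_id)) track_events(sec_id, "secondary")
  if (!is.na(turn_id)) track_events(turn_id, "main_contraction")

  structure(list(frames = frames, tracks = tracks, events = events,
                 main = main_id, secondary = sec_id,
                 main_contraction = turn_id,
                 threshold = threshold, delta = delta),
            class = "vortex_track")
}

#' @export
print.vortex_track <- function(x, ...) {
  cat(sprintf("vortex tracking: %d tracks; main = %s, secondary = %s\n",
              length(x$tracks),
              ifelse(is.na(x$main), "none", x$main),
              ifelse(is.na(x$secondary), "none", x$secondary)))
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

#' Grid-sensitivity analysis
#'
#' Reruns a scenario on a ladder of uniformly refined grids and reports, for
#' each consecutive pair, the average relative difference of the cut-point
#' speeds over the snapshot times (snapshots where the reference speeds are
#' essentially zero -- below `min_speed_frac` of the global maximum -- are
#' excluded from the relative comparison). The result is considered grid
#' independent at the coarsest level whose difference from the next
#' refinement is at most `criterion` percent.
#'
#' @param config Base [scenario_config()].
#' @param levels Number of grid levels (>= 2).
#' @param ratio Scenario used for the test (default `"3:1"`).
#' @param factor Linear refinement factor between levels.
#' @param criterion Acceptance threshold, percent.
#' @param min_speed_frac Relative floor below which speeds are excluded.
#' @return An object of class `sensitivity_report` with a `pairs`
#'   data.frame (cells, average relative difference in percent) and the
#'   chosen level.
#' @export
grid_sensitivity <- function(config, levels = 2, ratio = "3:1",
                             factor = sqrt(2), criterion = 10,
                             min_speed_frac = 0.01) {
  if (levels < 2) stop("need at least two grid levels")
  grids <- vector("list", levels)
  grids[[1]] <- config$grid
  for (l in 2:levels) grids[[l]] <- refine_grid(grids[[l - 1]], factor)
  runs <- lapply(grids, function(g) {
    cfg <- config; cfg$grid <- g
    run_scenario(cfg, ratio = ratio, store_fields = FALSE)
  })
  pairs <- data.frame(coarse_nr = integer(0), fine_nr = integer(0),
                      avg_rel_diff_pct = numeric(0))
  for (l in seq_len(levels - 1)) {
    tc <- runs[[l]]$traces; tf <- runs[[l + 1]]$traces
    floorv <- min_speed_frac * max(tf)
    per_snap <- vapply(seq_len(nrow(tf)), function(k) {
      ok <- tf[k, ] >= floorv
      if (!any(ok)) return(NA_real_)
      mean(abs(tc[k, ok] - tf[k, ok]) / tf[k, ok])
    }, numeric(1))
    pairs <- rbind(pairs, data.frame(
      coarse_nr = grids[[l]]$nr, fine_nr = grids[[l + 1]]$nr,
      avg_rel_diff_pct = 100 * mean(per_snap, na.rm = TRUE)))
  }
  chosen <- which(pairs$avg_rel_diff_pct <= criterion)
  structure(list(pairs = pairs, criterion = criterion,
                 chosen_nr = if (length(chosen)) pairs$coarse_nr[chosen[1]] else NA,
                 grids = vapply(grids, function(g) g$nr, integer(1))),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("grid sensitivity (average relative cut-point speed difference):\n")
  print(x$pairs, row.names = FALSE)
  cat(sprintf("criterion <= %g%%; chosen radial resolution: %s cells\n",
              x$criterion, ifelse(is.na(x$chosen_nr), "none", x$chosen_nr)))
  invisible(x)
}
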