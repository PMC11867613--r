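# Minimal base-graphics visualisation: cut-point traces and r-z field
# snapshots with log-magnitude arrows.

#' Plot cut-point velocity traces
#'
#' @param result A `simulation_result`.
#' @param file Optional PNG path; `NULL` draws on the current device.
#' @return Invisibly, `file`.
#' @export
plot_traces <- function(result, file = NULL) {
  if (!is.null(file)) grDevices::png(file, width = 900, height = 600)
  op <- graphics::par(mar = c(4, 4.5, 2, 1))
  on.exit({ graphics::par(op); if (!is.null(file)) grDevices::dev.off() })
  graphics::matplot(result$times, result$traces, type = "l", lty = 1,
                    col = grDevices::hcl.colors(ncol(result$traces), "Zissou 1"),
                    xlab = "time (s)", ylab = "speed (m/s)",
                    main = sprintf("cut-point speeds, scenario %s", result$label))
  graphics::abline(v = result$config$motion$T_exp, lty = 3)
  graphics::legend("topright", legend = colnames(result$traces), lty = 1,
                   col = grDevices::hcl.colors(ncol(result$traces), "Zissou 1"),
                   cex = 0.7, bty = "n")
  invisible(file)
}

#' Plot a flow-field snapshot with log-scaled arrows
#'
#' Arrow lengths are proportional to the natural logarithm of the velocity
#' magnitude over a dynamic range of `range_quotient`, so that the weak far
#' field remains visible next to the aperture jet.
#'
#' @param field A `flow_field`.
#' @param file Optional PNG path.
#' @param every Plot an arrow every `every` cells.
#' @param range_quotient Dynamic range of the log arrow scaling.
#' @param rmax,zmax Optional axis limits, mm.
#' @return Invisibly, `file`.
#' @export
plot_field <- function(field, file = NULL, every = 4, range_quotient = 1000,
                       rmax = NULL, zmax = NULL) {
  g <- field$grid
  if (!is.null(file)) grDevices::png(file, width = 700, height = 900)
  op <- graphics::par(mar = c(4, 4.5, 2, 1))
  on.exit({ graphics::par(op); if (!is.null(file)) grDevices::dev.off() })
  nr <- g$nr; nz <- g$nz
  urf <- rbind(0, field$u_r)
  uc_r <- (urf[-(nr + 1), ] + urf[-1, ]) / 2
  uzf <- cbind(0, field$u_z)
  uc_z <- (uzf[, -(nz + 1)] + uzf[, -1]) / 2
  ii <- seq(1, nr, by = every); jj <- seq(1, nz, by = every)
  R <- matrix(g$r_centers[ii], length(ii), length(jj))
  Z <- matrix(g$z_centers[jj], length(ii), length(jj), byrow = TRUE)
  U <- uc_r[ii, jj]; V <- uc_z[ii, jj]
  sp <- sqrt(U^2 + V^2)
  mx <- max(sp)
  plot(NA, xlim = c(0, rmax %||% g$radius_extent),
       ylim = c(0, zmax %||% g$height_extent), asp = 1,
       xlab = "r (mm)", ylab = "z (mm)",
       main = sprintf("flow at t = %.2f s (max %.2e m/s)", field$time, mx))
  solid <- which(field$chi >= 0.5, arr.ind = TRUE)
  graphics::points(g$r_centers[solid[, 1]], g$z_centers[solid[, 2]],
                   pch = 15, cex = 0.3, col = "grey70")
  if (mx > 0) {
    len <- pmax(0, log(sp / mx) + log(range_quotient)) / log(range_quotient)
    scl <- every * g$h * 1.5 * len / pmax(sp, 1e-300)
    ok <- sp > 0 & len > 0.02
    graphics::arrows(R[ok], Z[ok], R[ok] + U[ok] * scl[ok],
                     Z[ok] + V[ok] * scl[ok],
                     length = 0.02, col = "steelblue4")
  }
  invisible(file)
}
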