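#' Two-chamber cochlea geometry and staggered grid
#'
#' Builds the uncoiled, two-dimensional computational domain: two rectangular
#' chambers of height `h` stacked in y, separated by the basilar membrane on
#' the line y = 0 for x in \[0, L - helicotrema_len\], and connected through
#' the open helicotrema gap at the apical end.  All outer walls (including
#' the basal end, where the oval and round windows are treated as rigid
#' because the membrane motion is prescribed analytically) are rigid no-slip
#' boundaries.
#'
#' Velocity and pressure live on a marker-and-cell staggered grid: u on
#' vertical cell faces, v on horizontal faces (the membrane coincides with a
#' face row), pressure at cell centres.  The x spacing is uniform; the y
#' spacing grows geometrically away from the membrane from `dy_min` (default
#' a third of the Stokes layer \eqn{\sqrt{2\nu/\omega}} at `f_max`) up to
#' `dy_max`, so the oscillatory boundary layer at the membrane is resolved
#' with at least `stokes_cells` cells.
#'
#' @param L Domain length (m).
#' @param h Height of each chamber (m).
#' @param helicotrema_len Length of the apical gap where the membrane is
#'   absent (m); must be at least `2 * dx`.
#' @param dx Longitudinal grid spacing (m); rounded so that `L` and the
#'   membrane end fall on grid faces.
#' @param dy_min First cell height at the membrane (m); default resolves the
#'   Stokes layer at `f_max` with `stokes_cells` cells.
#' @param dy_max Cap on the cell height away from the membrane (m).
#' @param growth Geometric growth ratio of the y spacing.
#' @param f_max Highest frequency the grid must resolve (Hz).
#' @param fluid A [fluid_properties()] object (used for the Stokes-layer
#'   default of `dy_min`).
#' @param stokes_cells Minimum number of cells inside the Stokes layer.
#' @return An object of class `cochlea_geometry`.
#' @examples
#' geom <- cochlea_geometry(L = 2e-3, dx = 50e-6, f_max = 5e3)
#' @export
cochlea_geometry <- function(L = 7e-3, h = 0.5e-3, helicotrema_len = 0.5e-3,
                             dx = 20e-6, dy_min = NULL, dy_max = 25e-6,
                             growth = 1.2, f_max = 20e3,
                             fluid = fluid_properties(), stokes_cells = 3) {
  stopifnot(L > 0, h > 0, helicotrema_len > 0, helicotrema_len < L,
            dx > 0, growth > 1, dy_max > 0, stokes_cells >= 1)
  if (is.null(dy_min)) {
    # first `stokes_cells` geometrically growing cells fit inside the layer
    delta_nu <- stokes_layer_thickness(fluid, f_max)
    dy_min <- delta_nu * (growth - 1) / (growth^stokes_cells - 1)
  }
  if (helicotrema_len < 2 * dx)
    abort("`helicotrema_len` must span at least two grid cells")

  Nx <- max(8L, as.integer(round(L / dx)))
  dx <- L / Nx
  xf <- seq(0, L, length.out = Nx + 1L)
  xc <- (xf[-1] + xf[-(Nx + 1L)]) / 2

  # membrane ends on a face
  iLm <- as.integer(round((L - helicotrema_len) / dx))
  iLm <- min(max(iLm, 1L), Nx - 2L)
  Lm <- xf[iLm + 1L]

  # geometric y spacings, membrane outward, rescaled to fill h exactly
  sp <- c()
  d <- dy_min
  while (sum(sp) < h) {
    sp <- c(sp, min(d, dy_max))
    d <- d * growth
  }
  sp <- sp * (h / sum(sp))
  ny_ch <- length(sp)
  yf_up <- c(0, cumsum(sp))
  yf_up[ny_ch + 1L] <- h
  yf <- c(-rev(yf_up)[-(ny_ch + 1L)], yf_up)
  Ny <- 2L * ny_ch
  yc <- (yf[-1] + yf[-(Ny + 1L)]) / 2
  dyc <- diff(yf)
  jm <- ny_ch # membrane face row: yf[jm + 1] == 0

  structure(list(
    L = L, h = h, helicotrema_len = L - Lm, Lm = Lm, iLm = iLm,
    Nx = Nx, Ny = Ny, dx = dx, xf = xf, xc = xc,
    yf = yf, yc = yc, dyc = dyc, jm = jm, ny_ch = ny_ch,
    dy_min = sp[1L], dy_max = dy_max, growth = growth,
    f_max = f_max, stokes_cells = stokes_cells,
    mem_col = seq_len(Nx) <= iLm,       # cells whose y=0 face is membrane
    mem_xf = seq_len(Nx - 1L) < iLm     # interior u-faces with membrane wall
  ), class = "cochlea_geometry")
}

#' @export
print.cochlea_geometry <- function(x, ...) {
  cat("<cochlea_geometry>\n")
  cat(sprintf("  L = %.3g mm, h = %.3g mm per chamber, helicotrema %.3g mm\n",
              x$L * 1e3, x$h * 1e3, x$helicotrema_len * 1e3))
  cat(sprintf("  grid %d x %d cells (dx = %.3g um, dy %.3g-%.3g um)\n",
              x$Nx, x$Ny, x$dx * 1e6, min(x$dyc) * 1e6, max(x$dyc) * 1e6))
  invisible(x)
}

# refuse geometries that cannot resolve the Stokes layer at frequency f
check_resolution <- function(geom, fluid, f) {
  dnu <- stokes_layer_thickness(fluid, f)
  n_in_layer <- sum(cumsum(geom$dyc[(geom$jm + 1):geom$Ny]) <= dnu)
  if (n_in_layer < geom$stokes_cells)
    abort(sprintf(paste0("grid resolves the %.3g um Stokes layer at %.3g kHz ",
                         "with only %d cells (need >= %d); rebuild the ",
                         "geometry with a larger `f_max` or smaller `dy_min`"),
                  dnu * 1e6, f / 1e3, n_in_layer, geom$stokes_cells))
  invisible(TRUE)
}
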