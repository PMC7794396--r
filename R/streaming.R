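# The complex convective product C = (u_hat* . grad) u_hat evaluated at the
# staggered velocity nodes.  With physical fields Re[z e^{i omega t}], the
# time-averaged quadratic quantities all derive from C:
#   Reynolds forcing  F    = -(rho0/2) Re C
#   Stokes drift      u_sd = (1/2) Re[(i/omega) C] = -Im(C) / (2 omega)
convective_products <- function(field) {
  geom <- field$geom
  u <- field$u; v <- field$v
  Cu <- Conj(u) * ddx_u(geom, u) +
    Conj(v_at_u(geom, v)) * ddy_u(geom, u)
  Cv <- Conj(u_at_v(geom, u)) * ddx_v(geom, v) +
    Conj(v) * ddy_v(geom, v)
  list(Cu = Cu, Cv = Cv) # (Nx+1) x Ny and Nx x (Ny+1)
}

#' Reynolds-stress forcing of the mean flow
#'
#' The time-averaged momentum flux of the oscillatory flow acts as a steady
#' body force \eqn{F = -\rho_0 \langle (u_1\cdot\nabla) u_1\rangle =
#' -(\rho_0/2) Re[(\hat u^* \cdot \nabla)\hat u]} driving the Eulerian
#' streaming.  Cross-frequency products of distinct tones average to zero,
#' so each tone's forcing is computed from its own field.
#'
#' @param field An `oscillatory_field` from [solve_oscillatory()].
#' @return A list with matrices `Fu` ((Nx+1) x Ny, at u-nodes) and `Fv`
#'   (Nx x (Ny+1), at v-nodes), in N/m^3.
#' @export
reynolds_forcing <- function(field) {
  C <- convective_products(field)
  rho0 <- field$fluid$rho0
  list(Fu = -rho0 / 2 * Re(C$Cu), Fv = -rho0 / 2 * Re(C$Cv))
}

#' Stokes drift of an oscillatory field
#'
#' The difference between the mean velocity of a material particle and the
#' Eulerian mean at a fixed point:
#' \eqn{u_{sd} = \frac12 Re[(\hat\xi^* \cdot \nabla)\hat u]} with the fluid
#' displacement \eqn{\hat\xi = \hat u/(i\omega)}.  For a progressive wave
#' \eqn{u = U\cos(\omega t - kx)} this evaluates to the classical
#' \eqn{U^2 k/(2\omega)}, directed with the wave; it vanishes for a pure
#' standing wave and for spatially uniform oscillation.
#'
#' @param field An `oscillatory_field`.
#' @return A list with matrices `u_sd` ((Nx+1) x Ny) and `v_sd`
#'   (Nx x (Ny+1)), in m/s.
#' @export
stokes_drift <- function(field) {
  C <- convective_products(field)
  list(u_sd = -Im(C$Cu) / (2 * field$omega),
       v_sd = -Im(C$Cv) / (2 * field$omega))
}

#' Streaming boundary slip on the membrane
#'
#' The oscillatory solve imposes no slip on the *mean* (flat) membrane line,
#' but the physical no-slip condition holds on the *moving* membrane.
#' Taylor-expanding it about the mean line,
#' \eqn{0 = u(x,\eta,t) \approx u(x,0,t) + \eta\,\partial_y u}, leaves a
#' steady second-order tangential slip on the mean line
#' \eqn{\bar u(0) = -\langle(\xi_{bm}\cdot\nabla) u_1\rangle =
#'      -\frac12 Re[\hat\xi_{bm}^*\, \partial_y \hat u]}
#' with the membrane displacement \eqn{\hat\xi_{bm} = \hat V/(i\omega)},
#' evaluated one-sidedly (second order) on each side of the membrane.  The
#' normal component vanishes at the wall by continuity.
#'
#' @param field An `oscillatory_field`.
#' @return A list with `slip_up` and `slip_dn` (m/s), one value per interior
#'   u-face, zero off the membrane.
#' @export
boundary_slip <- function(field) {
  geom <- field$geom
  jm <- geom$jm; yc <- geom$yc; Nx <- geom$Nx
  # membrane displacement at interior u-faces
  xf_int <- geom$xf[2:Nx]
  xi_bm <- field$motion$interp(xf_int) / (1i * field$omega)
  xi_bm[!geom$mem_xf] <- 0

  wall_up <- c(0, as.vector(field$mem_u_up), 0)
  wall_dn <- c(0, as.vector(field$mem_u_dn), 0)
  # one-sided d(u)/dy at y = 0+ using wall value and the two nearest nodes
  a <- yc[jm + 1L]; b <- yc[jm + 2L]
  du_up <- (-(a + b) / (a * b)) * wall_up +
    (b / (a * (b - a))) * field$u[, jm + 1L] +
    (-a / (b * (b - a))) * field$u[, jm + 2L]
  a2 <- -yc[jm]; b2 <- -yc[jm - 1L]
  du_dn <- -((-(a2 + b2) / (a2 * b2)) * wall_dn +
               (b2 / (a2 * (b2 - a2))) * field$u[, jm] +
               (-a2 / (b2 * (b2 - a2))) * field$u[, jm - 1L])
  slip_up <- -0.5 * Re(Conj(xi_bm) * du_up[2:Nx])
  slip_dn <- -0.5 * Re(Conj(xi_bm) * du_dn[2:Nx])
  slip_up[!geom$mem_xf] <- 0
  slip_dn[!geom$mem_xf] <- 0
  list(slip_up = slip_up, slip_dn = slip_dn)
}

#' Steady streaming driven by one tone
#'
#' Solves the steady Stokes problem for the Eulerian mean flow,
#' \deqn{0 = -\nabla\bar p/\rho_0 + \nu\nabla^2\bar u + F/\rho_0,}
#' forced by the Reynolds stresses of the oscillatory field, with the
#' second-order boundary slip of [boundary_slip()] as the tangential wall
#' value on the membrane faces (optional) and no-slip rigid outer walls,
#' then adds the Stokes drift to form the Lagrangian mean
#' \eqn{u_{ss} = \bar u + u_{sd}} - the transport velocity experienced by
#' tracers, and the primary observable.
#'
#' Because the formulation is perturbative, the streaming response is
#' exactly quadratic in the stimulus amplitude at fixed damping.
#'
#' @param field An `oscillatory_field` from [solve_oscillatory()].
#' @param include_slip Include the membrane slip term (default TRUE).  The
#'   time-domain oracle keeps its membrane flat, so oracle comparisons set
#'   this to FALSE.
#' @param op Optional precomputed operator (from the oscillatory solve).
#' @return An object of class `streaming_field` with staggered matrices
#'   `u_euler`, `v_euler`, `u_sd`, `v_sd`, `u_ss`, `v_ss` (m/s), the
#'   pressure of the mean flow, and a `provenance` tibble of contributing
#'   tones.
#' @export
solve_streaming_single <- function(field, include_slip = TRUE, op = NULL) {
  stopifnot(inherits(field, "oscillatory_field"))
  geom <- field$geom
  if (is.null(op)) op <- field$op %||% assemble_stokes(geom, field$fluid)

  C <- convective_products(field)
  # kinematic body force f = F/rho0 = -Re(C)/2 at interior velocity nodes
  f_u <- -Re(C$Cu[2:geom$Nx, , drop = FALSE]) / 2
  f_v <- -Re(C$Cv[, 2:geom$Ny, drop = FALSE]) / 2

  if (include_slip) {
    sl <- boundary_slip(field)
  } else {
    sl <- list(slip_up = rep(0, geom$Nx - 1L), slip_dn = rep(0, geom$Nx - 1L))
  }

  b <- stokes_rhs(op, mem_v = rep(0, geom$Nx),
                  mem_u_up = sl$slip_up, mem_u_dn = sl$slip_dn,
                  f_u = f_u, f_v = f_v)
  z <- as.numeric(Matrix::solve(op$A0, Re(b)))
  sol <- unpack_solution(op, z, mem_v = rep(0, geom$Nx))

  sd <- list(u_sd = -Im(C$Cu) / (2 * field$omega),
             v_sd = -Im(C$Cv) / (2 * field$omega))
  prov <- tibble(f = field$omega / (2 * pi),
                 omega = field$omega,
                 max_mem_V = max(Mod(field$mem_v)))
  structure(list(geom = geom, fluid = field$fluid,
                 u_euler = sol$u, v_euler = sol$v, p = sol$p,
                 u_sd = sd$u_sd, v_sd = sd$v_sd,
                 u_ss = sol$u + sd$u_sd, v_ss = sol$v + sd$v_sd,
                 slip_up = sl$slip_up, slip_dn = sl$slip_dn,
                 include_slip = include_slip,
                 provenance = prov),
            class = "streaming_field")
}

#' Superpose streaming fields of distinct tones
#'
#' Time averaging annihilates cross-frequency products, so the steady
#' streaming of a multi-tone stimulus is the sum of the single-tone
#' streaming fields.  Duplicate frequencies are refused (their cross terms
#' would not average to zero).
#'
#' @param fields A list of `streaming_field` objects on the same grid.
#' @return A combined `streaming_field` with concatenated provenance.
#' @export
superpose_streaming <- function(fields) {
  stopifnot(length(fields) >= 1)
  if (length(fields) == 1L) return(fields[[1L]])
  freqs <- unlist(lapply(fields, function(f) f$provenance$f))
  if (anyDuplicated(signif(freqs, 12)))
    abort("duplicate frequencies: cross terms would not time-average to zero")
  dims <- vapply(fields, function(f) dim(f$u_euler), integer(2))
  if (any(dims != dims[, 1])) abort("fields must share one grid")
  out <- fields[[1L]]
  for (f in fields[-1L]) {
    for (nm in c("u_euler", "v_euler", "p", "u_sd", "v_sd", "u_ss", "v_ss",
                 "slip_up", "slip_dn"))
      out[[nm]] <- out[[nm]] + f[[nm]]
    out$provenance <- bind_rows(out$provenance, f$provenance)
  }
  out
}

#' Steady streaming for a full stimulus (tone or comb)
#'
#' The end-to-end pipeline: for each tone of the stimulus, solve the WKB
#' membrane wave (each tone with the damping of its own SPL), the
#' oscillatory chamber flow, and the second-order streaming problem; then
#' superpose.  The sparse operator is assembled once and shared.
#'
#' @param tones An `otostream_tones` tibble ([tone()], [comb_from_delta()]).
#' @param props [membrane_properties()].
#' @param geom [cochlea_geometry()].
#' @param fluid [fluid_properties()].
#' @param include_slip Include the membrane slip term (see
#'   [solve_streaming_single()]).
#' @param carrier Membrane drive variant, see [as_membrane_motion()].
#' @param quiet Suppress per-tone progress messages.
#' @return A `streaming_field`.
#' @examples
#' \donttest{
#' props <- membrane_properties()
#' geom <- cochlea_geometry(L = 3e-3, dx = 50e-6)
#' sf <- solve_streaming(tone(20e3, 80), props, geom)
#' glance(sf)
#' }
#' @export
solve_streaming <- function(tones, props, geom, fluid = fluid_properties(),
                            include_slip = TRUE,
                            carrier = c("active", "attenuated"),
                            quiet = TRUE) {
  stopifnot(nrow(tones) >= 1)
  carrier <- match.arg(carrier)
  op <- assemble_stokes(geom, fluid)
  fields <- vector("list", nrow(tones))
  for (i in seq_len(nrow(tones))) {
    tn <- tones[i, ]
    if (!quiet)
      message(sprintf("tone %d/%d: %.4g kHz @ %g dB SPL",
                      i, nrow(tones), tn$f / 1e3, tn$spl))
    wkb <- solve_wkb(props, tn, h = geom$h, rho0 = fluid$rho0,
                     x_max = geom$L)
    osc <- solve_oscillatory(geom, fluid,
                             as_membrane_motion(wkb, carrier = carrier),
                             op = op)
    fields[[i]] <- solve_streaming_single(osc, include_slip = include_slip,
                                          op = op)
  }
  superpose_streaming(fields)
}

#' @export
print.streaming_field <- function(x, ...) {
  sp <- max(sqrt(u_at_cc(x$geom, x$u_ss)^2 + v_at_cc(x$geom, x$v_ss)^2))
  cat(sprintf("<streaming_field> %d tone(s), max |u_ss| = %.3g nm/s\n",
              nrow(x$provenance), sp * 1e9))
  invisible(x)
}

#' @method tidy streaming_field
#' @export
tidy.streaming_field <- function(x, ...) {
  geom <- x$geom
  cols <- lapply(list(u_euler = x$u_euler, u_sd = x$u_sd, u_ss = x$u_ss),
                 function(m) as.vector(u_at_cc(geom, m)))
  cols_v <- lapply(list(v_euler = x$v_euler, v_sd = x$v_sd, v_ss = x$v_ss),
                   function(m) as.vector(v_at_cc(geom, m)))
  tibble(x = rep(geom$xc, geom$Ny),
         y = rep(geom$yc, each = geom$Nx),
         chamber = ifelse(rep(geom$yc, each = geom$Nx) > 0, "upper", "lower"),
         u_euler = cols$u_euler, v_euler = cols_v$v_euler,
         u_sd = cols$u_sd, v_sd = cols_v$v_sd,
         u_ss = cols$u_ss, v_ss = cols_v$v_ss)
}

#' @method glance streaming_field
#' @export
glance.streaming_field <- function(x, ...) {
  d <- tidy(x)
  sp <- sqrt(d$u_ss^2 + d$v_ss^2)
  i <- which.max(sp)
  tibble(n_tones = nrow(x$provenance),
         max_speed = max(sp), max_u_ss = max(abs(d$u_ss)),
         max_v_ss = max(abs(d$v_ss)),
         x_at_max = d$x[i], y_at_max = d$y[i])
}

#' Vertical profile of the streaming at a station
#'
#' Extracts \eqn{u_{ss}(y)}, \eqn{v_{ss}(y)} at the grid column nearest `x`,
#' mirroring profile cuts at the characteristic place.
#'
#' @param x A `streaming_field`.
#' @param at Longitudinal station (m).
#' @return A tibble with `y`, `u_ss`, `v_ss`, `u_euler`, `v_euler`, `u_sd`,
#'   `v_sd`.
#' @export
streaming_profile <- function(x, at) {
  geom <- x$geom
  i <- which.min(abs(geom$xc - at))
  tibble(y = geom$yc,
         u_ss = u_at_cc(geom, x$u_ss)[i, ],
         v_ss = v_at_cc(geom, x$v_ss)[i, ],
         u_euler = u_at_cc(geom, x$u_euler)[i, ],
         v_euler = v_at_cc(geom, x$v_euler)[i, ],
         u_sd = u_at_cc(geom, x$u_sd)[i, ],
         v_sd = v_at_cc(geom, x$v_sd)[i, ])
}

#' @method autoplot streaming_field
#' @export
autoplot.streaming_field <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$x * 1e3, .data$y * 1e3)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$u_ss * 1e9)) +
    ggplot2::scale_fill_gradient2(name = "u_ss (nm/s)") +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = "Lagrangian mean (steady streaming) flow",
                  subtitle = "red: apex-ward, blue: base-ward")
}
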