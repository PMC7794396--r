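#' Membrane motion driving the fluid
#'
#' A light container for the complex membrane velocity profile
#' \eqn{\hat V(x)} at one angular frequency; the physical motion is
#' \eqn{V(x,t) = Re[\hat V(x) e^{i\omega t}]}.  Usually produced from a
#' [solve_wkb()] solution, but any profile can be supplied (e.g. synthetic
#' envelopes for validation studies).
#'
#' @param x Positions (m) at which `V_hat` is sampled.
#' @param V_hat Complex velocity amplitudes (m/s).
#' @param omega Angular frequency (rad/s).
#' @return An object of class `membrane_motion`; calling it at new positions
#'   interpolates `V_hat` linearly (zero outside the sampled range).
#' @export
membrane_motion <- function(x, V_hat, omega) {
  stopifnot(length(x) == length(V_hat), omega > 0, !is.unsorted(x))
  fre <- approxfun(x, Re(V_hat), yleft = 0, yright = 0)
  fim <- approxfun(x, Im(V_hat), yleft = 0, yright = 0)
  structure(list(x = x, V_hat = V_hat, omega = omega,
                 interp = function(xx) fre(xx) + 1i * fim(xx)),
            class = "membrane_motion")
}

#' @rdname membrane_motion
#' @param wkb A `wkb_solution` from [solve_wkb()].
#' @param carrier How the WKB wave drives the membrane.  `"active"`
#'   (default): the amplitude follows the WKB envelope \eqn{V_0|Z_0/Z|^{3/4}}
#'   up to the characteristic place and the full evanescent decay beyond it
#'   - the behaviour of an active cochlea whose amplification offsets
#'   propagation losses basal to the place, and the variant that reproduces
#'   published travelling-wave shapes and streaming magnitudes.
#'   `"attenuated"`: the verbatim passive WKB solution including the full
#'   cumulative decay \eqn{e^{\int Im\,k\,dx}} everywhere.
#'
#' @details The analytic membrane wave is written in `+ c.c.` convention
#'   (physical amplitude \eqn{2|\hat V|}); the flow solvers use
#'   \eqn{Re[z e^{i\omega t}]} (amplitude \eqn{|z|}).  `as_membrane_motion()`
#'   converts between them, doubling the phasor.
#' @export
as_membrane_motion <- function(wkb, carrier = c("active", "attenuated")) {
  stopifnot(inherits(wkb, "wkb_solution"))
  carrier <- match.arg(carrier)
  omega <- attr(wkb, "tone")$omega
  membrane_motion(wkb$x, 2 * wkb_drive(wkb, carrier), omega)
}

# membrane velocity phasor in the analytic (+ c.c.) convention for either
# carrier variant
wkb_drive <- function(wkb, carrier) {
  if (carrier == "attenuated") return(wkb$V_hat)
  phase <- pracma::cumtrapz(wkb$x, Re(wkb$k))[, 1]
  log_att <- Re(pracma::cumtrapz(wkb$x, Im(wkb$k))[, 1])
  ip <- which.min(Mod(wkb$Z)) # characteristic place: impedance minimum
  Mod(wkb$V_env) * exp(pmin(log_att - log_att[ip], 0)) *
    exp(1i * (Arg(wkb$V_env) - phase))
}

#' Frequency-domain oscillatory Stokes flow in the two-chamber domain
#'
#' Solves the unsteady Stokes equations for a single harmonic,
#' \deqn{i\omega\hat u = -\nabla \hat p/\rho_0 + \nu \nabla^2 \hat u,\quad
#'       \nabla\cdot\hat u = 0,}
#' with no-slip rigid outer walls and the membrane motion imposed as a
#' transpiration boundary condition on the mean (flat) membrane line:
#' \eqn{\hat v = \hat V(x)} on both membrane faces (the membrane moving up
#' pushes the upper-chamber fluid up and pulls the lower-chamber fluid up),
#' \eqn{\hat u = 0} tangentially.  The flattening is justified because
#' membrane displacements (nm-um) are far smaller than the chamber height;
#' its second-order consequence, the streaming boundary slip, is restored in
#' [solve_streaming_single()].
#'
#' The discrete saddle-point system is solved by a sparse direct
#' factorization with the pressure pinned in one cell.
#'
#' @param geom A [cochlea_geometry()].
#' @param fluid A [fluid_properties()].
#' @param motion A [membrane_motion()] (or a `wkb_solution`, coerced
#'   automatically).
#' @param mem_u_up,mem_u_dn Optional tangential wall velocities on the upper
#'   and lower membrane faces (complex, one value per interior u-face), used
#'   by the oscillating-plate benchmark; default 0 (no slip).
#' @param op Optional precomputed operator from an earlier solve on the same
#'   geometry and fluid (reused across tones and levels).
#' @param check Check Stokes-layer resolution before solving.
#' @return An object of class `oscillatory_field`: complex matrices `u`
#'   ((Nx+1) x Ny at x-faces), `v` (Nx x (Ny+1) at y-faces), `p` (cell
#'   centres, Pa), plus `omega`, the boundary data, and the geometry.
#' @export
solve_oscillatory <- function(geom, fluid, motion, mem_u_up = NULL,
                              mem_u_dn = NULL, op = NULL, check = TRUE) {
  if (inherits(motion, "wkb_solution")) motion <- as_membrane_motion(motion)
  stopifnot(inherits(motion, "membrane_motion"))
  omega <- motion$omega
  if (check) check_resolution(geom, fluid, omega / (2 * pi))
  if (is.null(op)) op <- assemble_stokes(geom, fluid)

  mem_v <- motion$interp(geom$xc)
  mem_v[!geom$mem_col] <- 0
  if (is.null(mem_u_up)) mem_u_up <- rep(0 + 0i, geom$Nx - 1L)
  if (is.null(mem_u_dn)) mem_u_dn <- rep(0 + 0i, geom$Nx - 1L)

  b <- stokes_rhs(op, mem_v = mem_v, mem_u_up = mem_u_up,
                  mem_u_dn = mem_u_dn)
  z <- solve_oscillatory_system(op, omega, b)
  sol <- unpack_solution(op, z, mem_v = mem_v)

  structure(list(geom = geom, fluid = fluid, omega = omega,
                 u = sol$u, v = sol$v, p = sol$p,
                 mem_v = mem_v, mem_u_up = mem_u_up, mem_u_dn = mem_u_dn,
                 motion = motion, op = op),
            class = "oscillatory_field")
}

#' @export
print.oscillatory_field <- function(x, ...) {
  cat(sprintf("<oscillatory_field> f = %.4g kHz, max |u| = %.3g, max |v| = %.3g m/s\n",
              x$omega / (2 * pi) / 1e3, max(Mod(x$u)), max(Mod(x$v))))
  invisible(x)
}

#' Volume-conservation audit of an oscillatory field
#'
#' The complex volume flux leaving each chamber through the helicotrema
#' plane (at the apical end of the membrane) must equal the flux injected
#' through that chamber's membrane face, \eqn{\int \hat V dx}; both chambers
#' and the discrete divergence are checked.
#'
#' @param field An `oscillatory_field`.
#' @return A tibble with one row per chamber: membrane flux, helicotrema
#'   flux, and their relative mismatch.
#' @export
flux_audit <- function(field) {
  geom <- field$geom
  ipl <- geom$iLm + 1L # u-face row at x = Lm
  jup <- (geom$jm + 1L):geom$Ny
  jdn <- 1:geom$jm
  mem_flux <- sum(field$mem_v[geom$mem_col]) * geom$dx
  hel_up <- sum(field$u[ipl, jup] * geom$dyc[jup])
  hel_dn <- sum(field$u[ipl, jdn] * geom$dyc[jdn])
  denom <- max(Mod(mem_flux), .Machine$double.eps)
  tibble(chamber = c("upper", "lower"),
         membrane_flux = c(mem_flux, -mem_flux),
         helicotrema_flux = c(hel_up, hel_dn),
         rel_mismatch = c(Mod(hel_up - mem_flux), Mod(hel_dn + mem_flux)) / denom)
}

#' Energy-balance audit of an oscillatory field
#'
#' Time-averaged power input through the membrane faces,
#' \eqn{\int \frac12 Re[(\hat p^{(2)} - \hat p^{(1)}) \hat V^*] dx},
#' compared with the time-averaged viscous dissipation
#' \eqn{\rho_0\nu \int \langle |\nabla u|^2 \rangle dV} evaluated by
#' midpoint quadrature of the discrete velocity gradients.
#'
#' @param field An `oscillatory_field`.
#' @return A tibble with `power_in`, `dissipation` (W per unit depth) and
#'   their relative mismatch.
#' @export
energy_audit <- function(field) {
  geom <- field$geom; fl <- field$fluid
  jm <- geom$jm
  p_up <- field$p[, jm + 1L]
  p_dn <- field$p[, jm]
  # pressure work on the fluid: upper chamber gains p_up*V through its lower
  # boundary (outward normal -y), the lower chamber loses p_dn*V
  pin_w <- 0.5 * Re((p_up - p_dn) * Conj(field$mem_v)) * geom$dx
  power_in <- sum(pin_w[geom$mem_col])

  gx_u <- ddx_u(geom, field$u)
  gy_u <- ddy_u(geom, field$u)
  gx_v <- ddx_v(geom, field$v)
  gy_v <- ddy_v(geom, field$v)
  wu <- outer(c(geom$dx / 2, rep(geom$dx, geom$Nx - 1L), geom$dx / 2), geom$dyc)
  hv <- c(geom$dyc[1] / 2, (geom$dyc[-geom$Ny] + geom$dyc[-1]) / 2,
          geom$dyc[geom$Ny] / 2)
  wv <- outer(rep(geom$dx, geom$Nx), hv)
  dissipation <- fl$rho0 * fl$nu / 2 *
    (sum((Mod(gx_u)^2 + Mod(gy_u)^2) * wu) +
       sum((Mod(gx_v)^2 + Mod(gy_v)^2) * wv))
  tibble(power_in = power_in, dissipation = dissipation,
         rel_mismatch = abs(power_in - dissipation) /
           max(abs(power_in), .Machine$double.eps))
}

#' @method tidy oscillatory_field
#' @export
tidy.oscillatory_field <- function(x, ...) {
  geom <- x$geom
  ucc <- u_at_cc(geom, x$u); vcc <- v_at_cc(geom, x$v)
  tibble(x = rep(geom$xc, geom$Ny),
         y = rep(geom$yc, each = geom$Nx),
         chamber = ifelse(rep(geom$yc, each = geom$Nx) > 0, "upper", "lower"),
         u_re = Re(as.vector(ucc)), u_im = Im(as.vector(ucc)),
         v_re = Re(as.vector(vcc)), v_im = Im(as.vector(vcc)),
         u_abs = Mod(as.vector(ucc)), v_abs = Mod(as.vector(vcc)),
         p_abs = Mod(as.vector(x$p)))
}

#' @method autoplot oscillatory_field
#' @export
autoplot.oscillatory_field <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$x * 1e3, .data$y * 1e3,
                                  fill = .data$u_abs)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "|u| (m/s)") +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("Oscillatory flow, f = %.3g kHz",
                                  object$omega / 2 / pi / 1e3))
}
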