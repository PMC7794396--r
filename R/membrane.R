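#' Basilar-membrane mechanical properties
#'
#' Bundles the mechanical description of the basilar membrane used throughout
#' the package: exponential stiffness and mass profiles, a level-dependent
#' damping table, and the area of the transverse membrane strip that the
#' lumped stiffness/mass/damping refer to.  Defaults are calibrated to
#' measurements from the gerbil cochlea: a basal moving mass of 32 ng and
#' stiffness of 1 N/m, falling to 65 ng and 0.03 N/m at 7 mm from the base,
#' over a strip one hair cell wide (8 um) and 186 um broad.
#'
#' The profiles are \eqn{K(x) = K_0 e^{-x/l_K}} (strictly decreasing) and
#' \eqn{m(x) = m_0 e^{x/l_m}} (strictly increasing); the length scales are
#' derived from the measured endpoints with [fit_length_scales()].
#'
#' The damping \eqn{\xi} is spatially constant but depends on the sound
#' pressure level: the default table \{60, 80, 100\} dB SPL ->
#' \{10, 500, 2000\} nN s/m encodes the compressive nonlinearity of the
#' active cochlea (weak sounds are amplified, i.e. effectively less damped).
#'
#' @param m0 Basal moving mass of the strip (kg).
#' @param K0 Basal stiffness of the strip (N/m).
#' @param x_ref Reference apical position (m) at which `m_ref`, `K_ref` were
#'   measured.
#' @param m_ref,K_ref Mass (kg) and stiffness (N/m) at `x_ref`.
#' @param strip_width,strip_breadth Longitudinal width and transverse breadth
#'   of the membrane strip (m); their product is the strip area `A`.
#' @param xi_by_spl Named numeric vector mapping SPL (dB, names) to damping
#'   \eqn{\xi} (N s/m, values).
#' @return An object of class `membrane_properties`.
#' @examples
#' props <- membrane_properties()
#' props$l_K # ~2.0 mm
#' @export
membrane_properties <- function(m0 = 32e-12, K0 = 1,
                                x_ref = 7e-3, m_ref = 65e-12, K_ref = 0.03,
                                strip_width = 8e-6, strip_breadth = 186e-6,
                                xi_by_spl = c(`60` = 10e-9, `80` = 500e-9,
                                              `100` = 2000e-9)) {
  stopifnot(m0 > 0, K0 > 0, x_ref > 0, m_ref > m0, K_ref < K0, K_ref > 0,
            strip_width > 0, strip_breadth > 0)
  if (is.null(names(xi_by_spl)) || any(!is.finite(as.numeric(names(xi_by_spl)))))
    abort("`xi_by_spl` must be a numeric vector named by SPL in dB.")
  if (any(xi_by_spl <= 0)) abort("damping values must be positive")
  ls <- fit_length_scales(K0, K_ref, m0, m_ref, x_ref)
  structure(list(
    m0 = m0, K0 = K0, x_ref = x_ref, m_ref = m_ref, K_ref = K_ref,
    l_m = ls$l_m, l_K = ls$l_K,
    A = strip_width * strip_breadth,
    xi_by_spl = xi_by_spl[order(as.numeric(names(xi_by_spl)))]
  ), class = "membrane_properties")
}

#' @export
print.membrane_properties <- function(x, ...) {
  cat("<membrane_properties>\n")
  cat(sprintf("  m: %.3g -> %.3g kg over %.3g mm  (l_m = %.3g mm)\n",
              x$m0, x$m_ref, x$x_ref * 1e3, x$l_m * 1e3))
  cat(sprintf("  K: %.3g -> %.3g N/m over %.3g mm  (l_K = %.3g mm)\n",
              x$K0, x$K_ref, x$x_ref * 1e3, x$l_K * 1e3))
  cat(sprintf("  strip area A = %.4g m^2\n", x$A))
  cat(sprintf("  xi table: %s dB -> %s nN s/m\n",
              paste(names(x$xi_by_spl), collapse = "/"),
              paste(signif(x$xi_by_spl * 1e9, 3), collapse = "/")))
  invisible(x)
}

#' Exponential length scales from endpoint measurements
#'
#' Given stiffness and mass measured at the base and at one apical reference
#' position, returns the length scales of the exponential profiles
#' \eqn{K(x)=K_0 e^{-x/l_K}}, \eqn{m(x)=m_0 e^{x/l_m}}:
#' \eqn{l_K = x_{ref}/\ln(K_0/K_{ref})}, \eqn{l_m = x_{ref}/\ln(m_{ref}/m_0)}.
#'
#' @inheritParams membrane_properties
#' @return A list with elements `l_K` and `l_m` (m).
#' @examples
#' fit_length_scales(1, 0.03, 32e-12, 65e-12, 7e-3) # l_K ~ 2.0 mm, l_m ~ 9.9 mm
#' @export
fit_length_scales <- function(K0, K_ref, m0, m_ref, x_ref) {
  stopifnot(K0 > 0, K_ref > 0, m0 > 0, m_ref > 0, x_ref > 0)
  if (K_ref >= K0) abort("need K_ref < K0 (stiffness decreases apically)")
  if (m_ref <= m0) abort("need m_ref > m0 (mass increases apically)")
  list(l_K = x_ref / log(K0 / K_ref),
       l_m = x_ref / log(m_ref / m0))
}

#' Membrane stiffness and mass profiles
#'
#' @param props A [membrane_properties()] object.
#' @param x Longitudinal position(s) from the base (m).
#' @return Stiffness (N/m) or mass (kg) at `x`.
#' @export
membrane_stiffness <- function(props, x) props$K0 * exp(-x / props$l_K)

#' @rdname membrane_stiffness
#' @export
membrane_mass <- function(props, x) props$m0 * exp(x / props$l_m)

#' Peak pressure amplitude from sound pressure level
#'
#' Converts dB SPL (RMS re 20 uPa) to the peak pressure amplitude
#' \eqn{p_0 = \sqrt{2}\, \cdot 20\,\mu Pa \cdot 10^{SPL/20}} used as the basal
#' forcing amplitude of the travelling wave.
#'
#' @param spl Sound pressure level (dB SPL).
#' @return Peak pressure amplitude (Pa).
#' @examples
#' spl_to_pressure_amplitude(0)  # 2.828e-5 Pa peak (20 uPa RMS)
#' spl_to_pressure_amplitude(94) / sqrt(2) # ~1 Pa RMS
#' @export
spl_to_pressure_amplitude <- function(spl) {
  stopifnot(is.finite(spl))
  sqrt(2) * 20e-6 * 10^(spl / 20)
}

#' Level-dependent damping coefficient
#'
#' Looks up the damping \eqn{\xi} for a given SPL from the calibrated table in
#' `props`.  Between table entries, \eqn{\log \xi} is interpolated linearly in
#' SPL (i.e. log-log in pressure, since SPL is already logarithmic in
#' pressure).  Outside the table the endpoint value is used with a warning.
#'
#' @inheritParams membrane_stiffness
#' @param spl Sound pressure level (dB SPL).
#' @return Damping coefficient (N s/m).
#' @export
xi_for_spl <- function(props, spl) {
  tab_spl <- as.numeric(names(props$xi_by_spl))
  tab_xi <- as.numeric(props$xi_by_spl)
  vapply(spl, function(s) {
    if (s < min(tab_spl) || s > max(tab_spl)) {
      warn(sprintf(paste0("SPL %g dB outside the calibrated damping table ",
                          "[%g, %g] dB; clamping to the endpoint"),
                   s, min(tab_spl), max(tab_spl)))
      s <- min(max(s, min(tab_spl)), max(tab_spl))
    }
    exp(approx(tab_spl, log(tab_xi), xout = s)$y)
  }, numeric(1))
}

#' Complex basilar-membrane impedance
#'
#' \eqn{Z(x) = [i\omega m(x) + \xi - i K(x)/\omega] / A}, relating the
#' transmembrane pressure difference to the membrane velocity,
#' \eqn{\tilde V = \tilde p / Z}.  At the resonance place, where
#' \eqn{\omega^2 = K(x)/m(x)}, the reactive parts cancel and \eqn{Z = \xi/A}.
#'
#' @inheritParams membrane_stiffness
#' @param omega Angular frequency (rad/s), must be positive.
#' @param xi Damping coefficient (N s/m).
#' @return Complex impedance (Pa s/m), vectorised over `x`.
#' @examples
#' props <- membrane_properties()
#' impedance(props, 0, 2 * pi * 20e3, 500e-9) # ~ 336 - 2646i Pa s/m
#' @export
impedance <- function(props, x, omega, xi) {
  if (omega <= 0) abort("`omega` must be positive")
  (1i * omega * membrane_mass(props, x) + xi -
     1i * membrane_stiffness(props, x) / omega) / props$A
}
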