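#' Cochlear fluid properties
#'
#' Perilymph and endolymph are dilute ionic solutions; density and viscosity
#' are taken as those of water.
#'
#' @param rho0 Density (kg/m^3).
#' @param nu Kinematic viscosity (m^2/s).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho0 = 1000, nu = 1e-6) {
  stopifnot(rho0 > 0, nu > 0)
  structure(list(rho0 = rho0, nu = nu), class = "fluid_properties")
}

#' Oscillatory (Stokes) boundary-layer thickness
#'
#' \eqn{\delta_\nu = \sqrt{2\nu/\omega}}: the depth over which an oscillating
#' no-slip boundary entrains the fluid.  About 4 um at 20 kHz in water.
#'
#' @param fluid A [fluid_properties()] object.
#' @param f Frequency (Hz).
#' @return Thickness (m).
#' @export
stokes_layer_thickness <- function(fluid, f) sqrt(2 * fluid$nu / (2 * pi * f))
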