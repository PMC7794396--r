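#' WKB travelling-wave solution on the basilar membrane
#'
#' Solves the one-dimensional transmission-line model of the cochlear
#' travelling wave in the WKB (slowly-varying-medium) approximation.  The
#' transmembrane pressure \eqn{\tilde p(x)} obeys
#' \eqn{d^2\tilde p/dx^2 = 2 i \omega \rho_0 \tilde p /(Z h)} with the local
#' impedance \eqn{Z(x)} of [impedance()].  With the complex wavenumber
#' \deqn{k(x) = \sqrt{2 \omega \rho_0 / (i Z(x) h)},}
#' (branch with negative imaginary part, so the wave decays apically), the
#' WKB solution is
#' \deqn{\tilde p(x) = p_0 \sqrt{k_0/k(x)}\; e^{-i\int_0^x k\,dx'}, \qquad
#'       \tilde V = \tilde p / Z.}
#' Physical fields are \eqn{Re[\tilde z\, e^{i\omega t}]}; `p0` is the peak
#' basal pressure amplitude.
#'
#' The grid must resolve the local wavelength; by default a uniform grid is
#' refined until the spacing is below `wavelength_frac` of \eqn{2\pi/Re(k)}
#' everywhere (the phase integral uses the cumulative trapezoidal rule).
#' Nodes where the WKB self-consistency ratio
#' \eqn{|\hat p'/\hat p| / |k|} exceeds `consistency_tol` trigger a warning.
#'
#' @param props A [membrane_properties()] object.
#' @param tones An `otostream_tones` tibble (one row; see [tone()]).
#' @param h Chamber height (m).
#' @param rho0 Fluid density (kg/m^3).
#' @param x_max Apical end of the grid (m).
#' @param x_grid Optional explicit grid (monotone, starting at 0); overrides
#'   automatic refinement.
#' @param xi Damping (N s/m); default looked up from the tone's SPL via
#'   [xi_for_spl()].
#' @param wavelength_frac Maximum grid spacing as a fraction of the local
#'   wavelength (default 1/20).
#' @param consistency_tol Threshold for the WKB self-consistency warning.
#' @return A tibble of class `wkb_solution` with complex columns `k`, `Z`,
#'   `p_hat` (pressure amplitude envelope \eqn{p_0\sqrt{k_0/k}}), `p_tilde`
#'   (pressure including the accumulated carrier \eqn{e^{-i\int k}}),
#'   `V_hat` (membrane velocity phasor, including the carrier; this drives
#'   the 2-D flow), `V_env` (velocity amplitude envelope
#'   \eqn{\hat p/Z = V_0 (Z_0/Z)^{3/4}}, the slowly varying prefactor whose
#'   single global maximum marks the characteristic place at every level)
#'   and the real consistency ratio `wkb_ratio`.
#'   Attributes: `tone`, `props`, `h`, `rho0`, `xi`.
#' @examples
#' sol <- solve_wkb(membrane_properties(), tone(20e3, 80))
#' sol$x[which.max(Mod(sol$V_env))] * 1e3 # envelope peaks near 1.2 mm
#' @export
solve_wkb <- function(props, tones, h = 0.5e-3, rho0 = 1000, x_max = 7e-3,
                      x_grid = NULL, xi = NULL,
                      wavelength_frac = 1 / 20, consistency_tol = 0.3) {
  stopifnot(inherits(props, "membrane_properties"), nrow(tones) == 1)
  tn <- tones[1, ]
  if (is.null(xi)) xi <- xi_for_spl(props, tn$spl)
  stopifnot(xi > 0, h > 0, rho0 > 0)
  omega <- tn$omega

  k_of <- function(x) wkb_wavenumber(props, x, omega, xi, h, rho0)

  if (is.null(x_grid)) {
    n <- 512L
    repeat {
      x_grid <- seq(0, x_max, length.out = n)
      k <- k_of(x_grid)
      need <- 2 * pi / pmax(abs(Re(k)), abs(k) / 2) * wavelength_frac
      if (max(diff(x_grid)) <= min(need) || n >= 65536L) break
      n <- 2L * n
    }
  } else {
    if (x_grid[1] != 0 || any(diff(x_grid) <= 0))
      abort("`x_grid` must be strictly increasing and start at 0")
    k <- k_of(x_grid)
  }

  Z <- impedance(props, x_grid, omega, xi)
  k0 <- k[1]
  phase_int <- pracma::cumtrapz(x_grid, k)[, 1]
  p_hat <- tn$p0 * sqrt(k0 / k)
  carrier <- exp(-1i * phase_int + 1i * tn$phase)
  p_tilde <- p_hat * carrier
  V_hat <- p_tilde / Z

  # WKB self-consistency: |p_hat'/p_hat| / |k| must stay small
  dp <- num_grad(x_grid, p_hat)
  ratio <- Mod(dp / p_hat) / Mod(k)
  if (any(ratio > consistency_tol, na.rm = TRUE))
    warn(sprintf(paste0("WKB self-consistency ratio exceeds %.2g at %d of %d ",
                        "nodes (max %.2g); the envelope varies quickly there"),
                 consistency_tol, sum(ratio > consistency_tol, na.rm = TRUE),
                 length(ratio), max(ratio, na.rm = TRUE)))

  out <- tibble(x = x_grid, k = k, Z = Z, p_hat = p_hat,
                p_tilde = p_tilde, V_hat = V_hat, V_env = p_hat / Z,
                wkb_ratio = ratio)
  class(out) <- c("wkb_solution", class(out))
  attr(out, "tone") <- tn
  attr(out, "props") <- props
  attr(out, "h") <- h
  attr(out, "rho0") <- rho0
  attr(out, "xi") <- xi
  out
}

# complex wavenumber with the apically-decaying branch (Im k <= 0)
wkb_wavenumber <- function(props, x, omega, xi, h, rho0) {
  Z <- impedance(props, x, omega, xi)
  if (any(Z == 0)) abort("impedance vanishes on the grid")
  k <- sqrt(2 * omega * rho0 / (1i * Z * h))
  ifelse(Im(k) > 0, -k, k)
}

# centred first derivative on a (possibly nonuniform) grid, one-sided at ends
num_grad <- function(x, y) {
  n <- length(x)
  d <- y
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  d
}

#' Characteristic place of a frequency
#'
#' In `"resonance"` mode, returns the undamped resonance place solving
#' \eqn{\omega^2 = K(x)/m(x)} (closed form through the [tonotopic_map()]).
#' In `"peak"` mode (default), returns the argmax of the damped WKB membrane
#' velocity amplitude envelope \eqn{|V_0 (Z_0/Z(x))^{3/4}|} (the slowly
#' varying WKB prefactor, which peaks where \eqn{|Z|} is minimal), refined
#' by a parabolic fit through the three nodes around the discrete maximum.
#' The two modes agree closely at every calibrated damping; the fully
#' attenuated magnitude \eqn{|\tilde V|} (column `V_hat`) additionally
#' carries the accumulated decay \eqn{e^{\int Im\,k\,dx}}, which at strong
#' damping moves its own maximum basally all the way to the base.
#'
#' @inheritParams solve_wkb
#' @param f Frequency (Hz).
#' @param mode `"peak"` or `"resonance"`.
#' @param spl SPL used to pick the damping in peak mode (default 80 dB).
#' @return Place (m from the base).
#' @export
characteristic_place <- function(props, f, mode = c("peak", "resonance"),
                                 spl = 80, xi = NULL, h = 0.5e-3,
                                 rho0 = 1000, x_max = 7e-3) {
  mode <- match.arg(mode)
  map <- tonotopic_map(props)
  x_res <- place_for_frequency(map, f)
  if (x_res < 0 || x_res > x_max)
    abort(sprintf("frequency %g Hz maps outside [0, %g] m", f, x_max))
  if (mode == "resonance") return(x_res)
  sol <- solve_wkb(props, tone(f, spl), h = h, rho0 = rho0, x_max = x_max,
                   xi = xi)
  env <- Mod(sol$V_env)
  i <- which.max(env)
  if (i == 1L || i == nrow(sol)) return(sol$x[i])
  # parabolic refinement on log-envelope
  x3 <- sol$x[(i - 1):(i + 1)]
  y3 <- log(env[(i - 1):(i + 1)])
  denom <- (x3[1] - x3[2]) * (x3[1] - x3[3]) * (x3[2] - x3[3])
  a <- (x3[3] * (y3[2] - y3[1]) + x3[2] * (y3[1] - y3[3]) +
          x3[1] * (y3[3] - y3[2])) / denom
  b <- (x3[3]^2 * (y3[1] - y3[2]) + x3[2]^2 * (y3[3] - y3[1]) +
          x3[1]^2 * (y3[2] - y3[3])) / denom
  if (a >= 0) sol$x[i] else -b / (2 * a)
}

#' Membrane sensitivity curves across levels
#'
#' Computes the membrane displacement amplitude per unit applied pressure
#' (the sensitivity \eqn{|V| / (\omega p_0)}) for one frequency at several
#' sound levels, each with its calibrated damping, using the same drive
#' variant as the flow pipeline (see [as_membrane_motion()]).  Basal to the
#' peak the response is essentially linear (curves nearly coincide); near
#' the peak the larger damping at high levels makes the response
#' compressive and the peak broader, so the peak is sharper and the
#' sensitivity higher at low stimulation levels.
#'
#' @inheritParams solve_wkb
#' @param f Frequency (Hz).
#' @param spls Sound levels (dB SPL).
#' @param carrier Drive variant, as in [as_membrane_motion()].
#' @return A tibble with `x`, `spl`, `displacement` (m), `sensitivity`
#'   (m/Pa).
#' @export
sensitivity_curves <- function(props, f = 17e3, spls = c(60, 80, 100),
                               h = 0.5e-3, rho0 = 1000, x_max = 7e-3,
                               carrier = c("active", "attenuated")) {
  carrier <- match.arg(carrier)
  grid <- seq(0, x_max, by = 2e-6) # shared across levels for comparability
  purrr::map_dfr(spls, function(s) {
    sol <- solve_wkb(props, tone(f, s), h = h, rho0 = rho0, x_max = x_max,
                     x_grid = grid)
    tn <- attr(sol, "tone")
    disp <- Mod(wkb_drive(sol, carrier)) / tn$omega
    tibble(x = sol$x, spl = s, displacement = disp,
           sensitivity = disp / tn$p0)
  })
}

#' @method tidy wkb_solution
#' @export
tidy.wkb_solution <- function(x, ...) {
  sol <- x
  tibble(x = sol$x,
         k_re = Re(sol$k), k_im = Im(sol$k),
         p_abs = Mod(sol$p_tilde), p_arg = Arg(sol$p_tilde),
         V_abs = Mod(sol$V_hat), V_arg = Arg(sol$V_hat),
         wkb_ratio = sol$wkb_ratio)
}

#' @method glance wkb_solution
#' @export
glance.wkb_solution <- function(x, ...) {
  tn <- attr(x, "tone")
  i <- which.max(Mod(x$V_env))
  j <- which.max(Mod(x$V_hat))
  tibble(f = tn$f, spl = tn$spl, p0 = tn$p0, xi = attr(x, "xi"),
         peak_x = x$x[i], peak_V_env = Mod(x$V_env)[i],
         argmax_V = x$x[j], max_V = Mod(x$V_hat)[j],
         peak_displacement = Mod(x$V_hat)[i] / tn$omega,
         max_wkb_ratio = max(x$wkb_ratio, na.rm = TRUE))
}

#' @method autoplot wkb_solution
#' @export
autoplot.wkb_solution <- function(object, ...) {
  d <- tidy(object)
  dd <- tidyr::pivot_longer(
    dplyr::transmute(d, x = .data$x * 1e3,
                     `|V| (m/s)` = .data$V_abs,
                     `Re k (1/m)` = .data$k_re),
    -"x", names_to = "quantity")
  ggplot2::ggplot(dd, ggplot2::aes(.data$x, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "distance from base (mm)", y = NULL,
                  title = "Basilar-membrane travelling wave (WKB)")
}
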