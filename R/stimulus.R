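#' Pure-tone stimulus
#'
#' A stimulus is a tibble with one row per tone and columns `f` (Hz), `omega`
#' (rad/s), `spl` (dB SPL), `p0` (basal peak pressure amplitude, Pa) and
#' `phase` (rad).  All package functions that take a stimulus accept such a
#' tibble, so combs and pure tones share one representation and pipe
#' naturally through the WKB, flow and streaming stages.
#'
#' @param f Frequency (Hz), positive.
#' @param spl Sound pressure level (dB SPL).
#' @param phase Phase at the base (rad).
#' @return A one-row tibble of class `otostream_tones`.
#' @examples
#' tone(20e3, spl = 80)
#' @export
tone <- function(f, spl = 80, phase = 0) {
  stopifnot(all(f > 0), length(spl) %in% c(1L, length(f)),
            length(phase) %in% c(1L, length(f)))
  out <- tibble(f = f, omega = 2 * pi * f, spl = rep_len(spl, length(f)),
                p0 = spl_to_pressure_amplitude(rep_len(spl, length(f))),
                phase = rep_len(phase, length(f)))
  class(out) <- c("otostream_tones", class(out))
  out
}

#' Tonotopic map
#'
#' The logarithmic frequency-to-place map implied by exponential stiffness
#' and mass profiles.  The undamped resonance condition
#' \eqn{\omega^2 = K(x)/m(x)} gives
#' \eqn{x(f) = slope \cdot \ln(f_{base}/f)} with
#' \eqn{slope = 2/(1/l_K + 1/l_m)} and \eqn{f_{base} = \sqrt{K_0/m_0}/2\pi}
#' the frequency whose place is the base, x = 0.
#'
#' @param props A [membrane_properties()] object.
#' @return A list of class `tonotopic_map` with `slope` (m per log-frequency)
#'   and `f_base` (Hz).
#' @examples
#' map <- tonotopic_map(membrane_properties())
#' map$slope * 1e3 # ~3.3 mm
#' @export
tonotopic_map <- function(props) {
  structure(list(slope = tonotopic_slope(props),
                 f_base = sqrt(props$K0 / props$m0) / (2 * pi)),
            class = "tonotopic_map")
}

#' @rdname tonotopic_map
#' @export
tonotopic_slope <- function(props) 2 / (1 / props$l_K + 1 / props$l_m)

#' @param map A [tonotopic_map()].
#' @param f Frequency (Hz).
#' @rdname tonotopic_map
#' @export
place_for_frequency <- function(map, f) {
  stopifnot(all(f > 0))
  map$slope * log(map$f_base / f)
}

#' @param x Place (m from the base).
#' @rdname tonotopic_map
#' @export
place_to_frequency <- function(map, x) map$f_base * exp(-x / map$slope)

#' Multi-frequency tone comb
#'
#' Builds a comb of `n` tones whose successive frequencies differ by a
#' constant ratio \eqn{R > 1}, so that their basilar-membrane wave peaks are
#' a constant tonotopic distance \eqn{\delta = slope \cdot \ln R} apart.
#' Either the spacing `delta` or the ratio `R` may be given.  By default the
#' comb is anchored so that the place of its highest frequency is `x_top`
#' (0.25 mm), putting the whole comb as basally as possible while keeping
#' `n` peaks inside the domain; alternatively give `f1` (the lowest
#' frequency) explicitly.
#'
#' Peak spacings of 100 um or less are refused: two-tone suppression, which
#' this linear model does not capture, becomes important when neighbouring
#' waves overlap within their nonlinear peak regions.
#'
#' @param map A [tonotopic_map()].
#' @param n Number of tones (>= 1).
#' @param delta Tonotopic peak spacing (m); exclusive with `R`.
#' @param R Successive frequency ratio (> 1); exclusive with `delta`.
#' @param spl Per-tone SPL (dB), length 1 or `n`.
#' @param f1 Lowest frequency (Hz); overrides `x_top` anchoring.
#' @param x_top Place of the highest-frequency peak (m) used to anchor the
#'   comb when `f1` is not given.
#' @param phase Per-tone phase (rad), length 1 or `n`; see
#'   [randomize_phases()].
#' @param x_max Apical end of the usable domain (m); combs whose lowest
#'   frequency peaks beyond it are refused.
#' @param min_delta Smallest admissible spacing (m).
#' @return An `otostream_tones` tibble with attributes `R` and `delta`.
#' @examples
#' map <- tonotopic_map(membrane_properties())
#' comb_from_delta(map, n = 10, delta = 330e-6, spl = 80)
#' @export
comb_from_delta <- function(map, n, delta = NULL, R = NULL, spl = 80,
                            f1 = NULL, x_top = 0.25e-3, phase = 0,
                            x_max = 7e-3, min_delta = 100e-6) {
  stopifnot(n >= 1)
  if (is.null(delta) == is.null(R))
    abort("give exactly one of `delta` or `R`")
  if (is.null(R)) {
    stopifnot(delta > 0)
    R <- exp(delta / map$slope)
  } else {
    stopifnot(R > 1)
    delta <- map$slope * log(R)
  }
  if (n > 1 && delta <= min_delta)
    abort(sprintf(paste0("peak spacing %.3g um is at or below %.3g um, where ",
                         "two-tone suppression invalidates the linear model"),
                  delta * 1e6, min_delta * 1e6))
  if (is.null(f1)) {
    f_top <- place_to_frequency(map, x_top)
    f1 <- f_top / R^(n - 1)
  }
  f <- f1 * R^(seq_len(n) - 1)
  if (place_for_frequency(map, f1) > x_max)
    abort("comb extends beyond the apical end of the domain")
  if (place_for_frequency(map, f[n]) < 0)
    abort("highest comb frequency peaks basal to x = 0")
  out <- tone(f, spl = spl, phase = phase)
  attr(out, "R") <- R
  attr(out, "delta") <- delta
  out
}

#' Peak places of a tone comb
#'
#' @param tones An `otostream_tones` tibble.
#' @param map A [tonotopic_map()].
#' @return A tibble with `f`, `x` (resonance-mode place, m), sorted by
#'   frequency; places decrease by the comb spacing `delta`.
#' @export
comb_places <- function(tones, map) {
  tibble(f = sort(tones$f), x = place_for_frequency(map, sort(tones$f)))
}

#' Randomize the per-tone phases of a stimulus
#'
#' Steady streaming from tones of distinct frequencies is phase-independent
#' after time averaging (cross-frequency products average to zero), so the
#' phases mainly matter for time-domain validation runs.  Deterministic
#' given `seed`.
#'
#' @param tones An `otostream_tones` tibble.
#' @param seed Integer seed.
#' @return The same tibble with uniformly random phases in \[0, 2pi).
#' @export
randomize_phases <- function(tones, seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  tones$phase <- stats::runif(nrow(tones), 0, 2 * pi)
  tones
}
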