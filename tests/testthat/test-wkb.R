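# WKB travelling-wave solution: basal values, branch, linearity,
# self-consistency, characteristic place, level-dependent sensitivity

test_that("WKB solution honours basal conditions and the decaying branch", {
  props <- std_props()
  sol <- solve_wkb(props, tone(20e3, 80))
  tn <- attr(sol, "tone")
  expect_equal(Mod(sol$p_hat[1]), tn$p0)
  expect_equal(sol$V_hat[1], tn$p0 / sol$Z[1])
  expect_true(all(Im(sol$k) <= 0))
  # amplitude of the accumulated carrier never increases apically
  carrier <- Mod(sol$p_tilde / sol$p_hat)
  expect_true(all(diff(carrier) <= 1e-12))
})

test_that("spatially constant impedance gives a single decaying wave", {
  props <- std_props()
  # flat profiles: enormous length scales
  props$l_K <- 1e6; props$l_m <- 1e6
  sol <- solve_wkb(props, tone(20e3, 80), x_max = 1e-3)
  expect_lt(diff(range(Mod(sol$k))) / Mod(sol$k[1]), 1e-6)
  expect_lt(diff(range(Mod(sol$p_hat))) / Mod(sol$p_hat[1]), 1e-6)
  # |p~| = p0 e^{Im k * x}
  expect_equal(Mod(sol$p_tilde), Mod(sol$p_hat[1]) * exp(Im(sol$k[1]) * sol$x),
               tolerance = 1e-6)
})

test_that("membrane response is linear in the stimulus amplitude", {
  props <- std_props()
  s1 <- solve_wkb(props, tone(17e3, 80), xi = 500e-9)
  t2 <- tone(17e3, 80); t2$p0 <- 2 * t2$p0
  s2 <- solve_wkb(props, t2, xi = 500e-9)
  expect_equal(s2$V_hat, 2 * s1$V_hat, tolerance = 1e-12)
})

test_that("characteristic place sits near 1.2 mm for 20 kHz at every level", {
  props <- std_props()
  for (xi in c(10e-9, 500e-9, 2000e-9))
    expect_equal(characteristic_place(props, 20e3, xi = xi) * 1e3, 1.13,
                 tolerance = 0.01)
  expect_equal(characteristic_place(props, 20e3, mode = "resonance") * 1e3,
               1.133, tolerance = 0.001)
  # peak and resonance modes agree
  expect_equal(characteristic_place(props, 17e3),
               characteristic_place(props, 17e3, mode = "resonance"),
               tolerance = 1e-3)
  expect_error(characteristic_place(props, 100e3), "outside")
})

test_that("sensitivity curves coincide basally and compress near the peak", {
  props <- std_props()
  sens <- sensitivity_curves(props, f = 17e3, spls = c(60, 80, 100))
  w <- tidyr::pivot_wider(sens[, c("x", "spl", "sensitivity")],
                          names_from = "spl", values_from = "sensitivity")
  # basal region: near-level-independent (linear response; the 100-dB
  # damping is a small but not negligible share of the basal reactance)
  basal <- w[w$x < 0.4e-3, ]
  basal_dev <- max(abs(basal$`60` / basal$`100` - 1))
  expect_lt(basal_dev, 0.1)
  # peak sensitivity decreases with level (compressive nonlinearity) and
  # the divergence near the peak dwarfs the basal one
  peaks <- vapply(c("60", "80", "100"), function(s) max(w[[s]]), numeric(1))
  expect_true(all(diff(peaks) < 0))
  expect_gt(peaks[["60"]] / peaks[["100"]], 1 + 10 * basal_dev)
})

test_that("WKB residual in the pressure equation shrinks for slower profiles", {
  props <- std_props()
  resid <- function(p) {
    sol <- solve_wkb(p, tone(20e3, 80), xi = 500e-9, x_max = 3e-3)
    d2p <- otostream:::num_grad(sol$x, otostream:::num_grad(sol$x, sol$p_tilde))
    rhs <- 2i * attr(sol, "tone")$omega * attr(sol, "rho0") * sol$p_tilde /
      (sol$Z * attr(sol, "h"))
    win <- sol$x > 0.3e-3 & sol$x < 0.9e-3 # propagating region
    stats::median(Mod(d2p - rhs)[win] / Mod(rhs)[win])
  }
  r1 <- resid(props)
  slow <- membrane_properties(K_ref = props$K0 * (props$K_ref / props$K0)^0.5,
                              m_ref = props$m0 * (props$m_ref / props$m0)^0.5)
  # length scales doubled -> slower impedance variation -> smaller residual
  expect_equal(slow$l_K, 2 * props$l_K, tolerance = 1e-10)
  expect_lt(resid(slow), r1)
  expect_lt(r1, 0.1) # residual itself is small where WKB is valid
})

test_that("grid refinement triggers on short local wavelengths", {
  props <- std_props()
  sol <- solve_wkb(props, tone(20e3, 80))
  lam <- 2 * pi / pmax(abs(Re(sol$k)), Mod(sol$k) / 2)
  expect_lt(max(diff(sol$x)) / min(lam), 1 / 20 + 1e-9)
  expect_error(solve_wkb(props, tone(20e3, 80), x_grid = c(0.1e-3, 0.2e-3)),
               "start at 0")
})
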