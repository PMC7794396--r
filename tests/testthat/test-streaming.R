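# Second-order streaming: drift closed forms (against a brute-force
# trajectory oracle), forcing, slip, scaling laws, superposition

test_that("Stokes drift of a progressive wave is U^2 k / (2 omega)", {
  geom <- plain_geom()
  U <- 1e-3; k <- 2000; omega <- 2 * pi * 500
  fld <- synthetic_field(geom,
                         fu = function(x, y) U * exp(-1i * k * x),
                         fv = function(x, y) 0 * x + 0i, omega = omega)
  sd <- stokes_drift(fld)
  expected <- U^2 * k / (2 * omega)
  mid <- round(geom$Nx / 2)
  expect_equal(sd$u_sd[mid, 5], expected, tolerance = 0.005)
  expect_equal(max(abs(sd$v_sd)), 0)

  # independent oracle: brute-force trajectory averaging in the analytic
  # time-dependent field (convention-fixing test: apex-ward wave drifts
  # apex-ward)
  bd <- brute_drift(function(x, y, t) U * cos(omega * t - k * x),
                    function(x, y, t) 0, omega,
                    x0 = 1e-3, y0 = 0.1e-3)
  expect_equal(bd[1], expected, tolerance = 0.01)
  expect_gt(bd[1], 0)
})

test_that("standing waves and uniform oscillation produce no drift", {
  geom <- plain_geom()
  U <- 1e-3; k <- 2000; omega <- 2 * pi * 500
  standing <- synthetic_field(geom,
                              fu = function(x, y) U * cos(k * x) + 0i,
                              fv = function(x, y) 0 * x + 0i, omega = omega)
  sd <- stokes_drift(standing)
  expect_equal(max(abs(sd$u_sd)), 0)
  bd <- brute_drift(function(x, y, t) U * cos(k * x) * cos(omega * t),
                    function(x, y, t) 0, omega, x0 = 1e-3, y0 = 0.1e-3)
  expect_lt(abs(bd[1]), 1e-3 * U^2 * k / (2 * omega) + 1e-12)

  uniform <- synthetic_field(geom,
                             fu = function(x, y) U + 0i,
                             fv = function(x, y) 0 * x + 0i, omega = omega)
  expect_equal(max(abs(stokes_drift(uniform)$u_sd)), 0)
  expect_equal(max(abs(reynolds_forcing(uniform)$Fu)), 0)
})

test_that("Reynolds forcing matches symbolic derivatives of a layer profile", {
  # fine vertical grid so the discrete gradient is accurate to < 1%
  geom <- cochlea_geometry(L = 2e-3, h = 0.3e-3, helicotrema_len = 0.4e-3,
                           dx = 25e-6, dy_min = 4e-6, dy_max = 6e-6,
                           growth = 1.05, f_max = 1e3)
  U <- 1e-3; omega <- 2 * pi * 100
  rho0 <- std_fluid()$rho0
  dnu <- sqrt(2 * std_fluid()$nu / omega)
  uhat <- function(y) U * exp(-(1 + 1i) * (y + geom$h) / dnu)
  # x-independent Stokes layer with no vertical flow: (u* . grad) u = 0
  fld <- synthetic_field(geom, fu = function(x, y) uhat(y),
                         fv = function(x, y) 0 * x + 0i, omega = omega)
  expect_lt(max(abs(reynolds_forcing(fld)$Fu)) / (rho0 * U^2 / dnu), 1e-10)

  # add a uniform vertical phasor: F_u = -(rho0/2) Re[v* du/dy], checked
  # against the exact derivative of the layer profile on the stretched grid
  V0 <- (2e-4) * exp(1i * pi / 3)
  fld2 <- synthetic_field(geom, fu = function(x, y) uhat(y),
                          fv = function(x, y) 0 * x + V0, omega = omega)
  Fu <- reynolds_forcing(fld2)$Fu
  j <- 4L # inside the layer, stencil clear of the wall
  exact <- -(rho0 / 2) *
    Re(Conj(V0) * (-(1 + 1i) / dnu) * uhat(geom$yc[j]))
  expect_equal(Fu[10, j], exact, tolerance = 0.03)
})

test_that("boundary slip is quadratic in the wave and zero for rigid motion", {
  fld <- small_field()
  sl <- boundary_slip(fld)
  expect_true(any(sl$slip_up != 0))
  # scaling the wave by s scales the slip by s^2
  fld2 <- solve_oscillatory(small_geom(), std_fluid(), gauss_motion(V0 = 3e-4),
                            op = small_op())
  sl2 <- boundary_slip(fld2)
  expect_equal(sl2$slip_up, 9 * sl$slip_up, tolerance = 1e-9)
  expect_equal(sl2$slip_dn, 9 * sl$slip_dn, tolerance = 1e-9)

  # rigid vertical oscillation of fluid + membrane: du/dy = 0 -> no slip
  geom <- small_geom()
  rigid <- structure(list(geom = geom, fluid = std_fluid(),
                          omega = 2 * pi * 1e3,
                          u = matrix(0 + 0i, geom$Nx + 1, geom$Ny),
                          v = matrix(1e-4 + 0i, geom$Nx, geom$Ny + 1),
                          mem_u_up = rep(0 + 0i, geom$Nx - 1),
                          mem_u_dn = rep(0 + 0i, geom$Nx - 1),
                          motion = membrane_motion(c(0, geom$L),
                                                   c(1e-4 + 0i, 1e-4 + 0i),
                                                   2 * pi * 1e3)),
                     class = "oscillatory_field")
  sl0 <- boundary_slip(rigid)
  expect_equal(max(abs(sl0$slip_up)), 0)
  expect_equal(max(abs(sl0$slip_dn)), 0)
})

test_that("streaming is exactly quadratic in the stimulus amplitude", {
  f1 <- small_field()
  s1 <- solve_streaming_single(f1, op = small_op())
  f2 <- solve_oscillatory(small_geom(), std_fluid(), gauss_motion(V0 = 3e-4),
                          op = small_op())
  s2 <- solve_streaming_single(f2, op = small_op())
  expect_equal(s2$u_ss, 9 * s1$u_ss, tolerance = 1e-12)
  expect_equal(s2$v_ss, 9 * s1$v_ss, tolerance = 1e-12)

  # the x300 amplitude trick: scale up, solve, scale the streaming back down
  f300 <- solve_oscillatory(small_geom(), std_fluid(),
                            gauss_motion(V0 = 300 * 1e-4), op = small_op())
  s300 <- solve_streaming_single(f300, op = small_op())
  expect_equal(s300$u_ss / 300^2, s1$u_ss, tolerance = 1e-12)
})

test_that("zero forcing and zero slip give zero streaming", {
  geom <- small_geom()
  still <- membrane_motion(c(0, geom$L), c(0 + 0i, 0 + 0i), 2 * pi * 20e3)
  fld <- solve_oscillatory(geom, std_fluid(), still, op = small_op())
  sf <- solve_streaming_single(fld, op = small_op())
  expect_equal(max(abs(sf$u_ss)), 0)
  expect_equal(max(abs(sf$v_ss)), 0)
})

test_that("multi-tone streaming superposes single-tone fields", {
  props <- std_props()
  map <- tonotopic_map(props)
  comb <- comb_from_delta(map, n = 3, delta = 500e-6, spl = 80,
                          f1 = 12e3)
  geom <- cochlea_geometry(L = 4e-3, dx = 60e-6, f_max = max(comb$f),
                           growth = 1.3)
  fl <- std_fluid()
  sf_comb <- solve_streaming(comb, props, geom, fl)
  singles <- lapply(seq_len(3), function(i)
    solve_streaming(comb[i, ], props, geom, fl))
  manual <- superpose_streaming(singles)
  expect_equal(sf_comb$u_ss, manual$u_ss, tolerance = 1e-12)
  expect_equal(nrow(sf_comb$provenance), 3L)

  # permutation invariance and duplicate refusal
  perm <- superpose_streaming(singles[c(2, 3, 1)])
  expect_equal(perm$u_ss, manual$u_ss, tolerance = 1e-12)
  expect_error(superpose_streaming(singles[c(1, 1)]), "duplicate")
})

test_that("streaming profile shape is level-independent at fixed damping", {
  # at fixed damping the whole second-order field scales as p0^2, so the
  # peak-normalized profile at the characteristic place is identical across
  # levels (with the calibrated level-dependent damping table the drive's
  # spatial structure itself changes between levels, which reshapes the
  # vortex; see the methods vignette)
  props <- std_props(); fl <- std_fluid()
  geom <- coarse_geom()
  xstar <- characteristic_place(props, 20e3)
  op <- otostream:::assemble_stokes(geom, fl)
  profs <- lapply(c(80, 94), function(spl) {
    wkb <- solve_wkb(props, tone(20e3, spl), xi = 500e-9, h = geom$h,
                     rho0 = fl$rho0, x_max = geom$L)
    osc <- solve_oscillatory(geom, fl, as_membrane_motion(wkb), op = op)
    sf <- solve_streaming_single(osc, op = op)
    pr <- streaming_profile(sf, xstar)
    up <- pr[pr$y > 0, ]
    up$u_ss / max(abs(up$u_ss))
  })
  expect_lt(max(abs(profs[[1]] - profs[[2]])), 1e-9)
})
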