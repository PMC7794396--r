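# Oscillatory Stokes solver: benchmark, conservation, symmetry, guards

test_that("flat-plate oscillation reproduces the Stokes boundary layer", {
  geom <- small_geom(); fl <- std_fluid()
  U <- 1e-3
  still <- membrane_motion(c(0, geom$L), c(0 + 0i, 0 + 0i), 2 * pi * 20e3)
  fld <- solve_oscillatory(geom, fl, still,
                           mem_u_up = rep(U + 0i, geom$Nx - 1L),
                           mem_u_dn = rep(U + 0i, geom$Nx - 1L),
                           op = small_op())
  dnu <- stokes_layer_thickness(fl, 20e3)
  expect_equal(dnu * 1e6, 3.99, tolerance = 0.01)
  icol <- round(geom$Nx * 0.4)
  jj <- (geom$jm + 1):(geom$jm + 6) # inside ~2 delta_nu
  yy <- geom$yc[jj]
  prof <- fld$u[icol, jj]
  exact <- U * exp(-(1 + 1i) * yy / dnu)
  expect_lt(max(Mod(prof - exact)) / U, 0.02)
})

test_that("zero membrane motion gives a zero field", {
  geom <- small_geom()
  still <- membrane_motion(c(0, geom$L), c(0 + 0i, 0 + 0i), 2 * pi * 20e3)
  fld <- solve_oscillatory(geom, std_fluid(), still, op = small_op())
  expect_equal(max(Mod(fld$u)), 0)
  expect_equal(max(Mod(fld$v)), 0)
  fa <- flux_audit(fld)
  expect_equal(Mod(fa$helicotrema_flux), c(0, 0))
})

test_that("solved fields conserve volume and satisfy continuity", {
  fld <- small_field()
  geom <- fld$geom
  fa <- flux_audit(fld)
  expect_lt(max(fa$rel_mismatch), 1e-6)
  div <- (fld$u[2:(geom$Nx + 1), ] - fld$u[1:geom$Nx, ]) / geom$dx +
    sweep(fld$v[, 2:(geom$Ny + 1)] - fld$v[, 1:geom$Ny], 2, geom$dyc, "/")
  div_scale <- max(Mod(fld$u)) / geom$dx
  # every cell except the pinned one is divergence-free to solver precision
  expect_lt(sort(Mod(as.vector(div)), decreasing = TRUE)[2] / div_scale, 1e-10)
})

test_that("response is linear in the membrane amplitude", {
  geom <- small_geom()
  f1 <- small_field()
  f2 <- solve_oscillatory(geom, std_fluid(), gauss_motion(V0 = 2e-4),
                          op = small_op())
  expect_lt(max(Mod(f2$u - 2 * f1$u)) / max(Mod(f1$u)), 1e-10)
  fa1 <- flux_audit(f1); fa2 <- flux_audit(f2)
  expect_equal(fa2$helicotrema_flux, 2 * fa1$helicotrema_flux,
               tolerance = 1e-10)
})

test_that("symmetric chambers mirror each other around the membrane", {
  fld <- small_field()
  geom <- fld$geom
  # u antisymmetric, v symmetric under y -> -y for a single membrane motion
  cols_up <- (geom$jm + 1):geom$Ny
  cols_dn <- geom$jm:1
  scale_u <- max(Mod(fld$u))
  expect_lt(max(Mod(fld$u[, cols_up] + fld$u[, cols_dn])) / scale_u, 1e-10)
  rows_v_up <- (geom$jm + 2):(geom$Ny + 1)
  rows_v_dn <- geom$jm:1
  scale_v <- max(Mod(fld$v))
  expect_lt(max(Mod(fld$v[, rows_v_up] - fld$v[, rows_v_dn])) / scale_v, 1e-10)
})

test_that("power input balances viscous dissipation", {
  ea <- energy_audit(small_field())
  expect_lt(ea$rel_mismatch, 0.01)
  expect_gt(ea$power_in, 0)
})

test_that("field values at probes converge under grid refinement", {
  fl <- std_fluid()
  probe_vals <- function(dx, dy_min) {
    geom <- cochlea_geometry(L = 2e-3, h = 0.3e-3, helicotrema_len = 0.4e-3,
                             dx = dx, dy_min = dy_min, f_max = 20e3)
    fld <- solve_oscillatory(geom, fl, gauss_motion())
    smp <- otostream:::flow_sampler(geom, fld$u, fld$v)
    smp(c(0.6e-3, 0.8e-3, 1.0e-3), c(0.1e-3, -0.15e-3, 0.05e-3))
  }
  a <- probe_vals(25e-6, NULL)
  b <- probe_vals(12.5e-6, 0.66e-6)
  expect_lt(max(Mod(a - b)) / max(Mod(b)), 0.02)
})

test_that("insufficient resolution and degenerate geometry are refused", {
  fl <- std_fluid()
  geom_lo <- cochlea_geometry(L = 2e-3, h = 0.3e-3, helicotrema_len = 0.4e-3,
                              dx = 50e-6, f_max = 1e3)
  expect_error(solve_oscillatory(geom_lo, fl, gauss_motion(f = 20e3)),
               "Stokes layer")
  # no helicotrema -> two disconnected chambers cannot balance flux
  expect_error(cochlea_geometry(L = 2e-3, helicotrema_len = 0), ">")
  expect_error(cochlea_geometry(L = 2e-3, dx = 50e-6,
                                helicotrema_len = 60e-6), "two grid cells")
})
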