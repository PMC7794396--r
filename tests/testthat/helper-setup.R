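# Shared fixtures, memoised across test files (helpers are sourced once per
# test run).  Everything is built in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())
fx <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

std_props <- function() fx("props", membrane_properties)
std_fluid <- function() fx("fluid", fluid_properties)

# small two-chamber geometry resolving 20 kHz, for solver unit tests
small_geom <- function() fx("small_geom", function()
  cochlea_geometry(L = 2e-3, h = 0.3e-3, helicotrema_len = 0.4e-3,
                   dx = 50e-6, f_max = 20e3))

small_op <- function() fx("small_op", function()
  otostream:::assemble_stokes(small_geom(), std_fluid()))

# coarse full-length geometry for qualitative single-tone streaming
coarse_geom <- function() fx("coarse_geom", function()
  cochlea_geometry(L = 7e-3, dx = 50e-6, f_max = 20e3, growth = 1.3))

# synthetic Gaussian travelling-wave membrane motion on the small geometry
gauss_motion <- function(V0 = 1e-4, f = 20e3) {
  xs <- seq(0, 2e-3, length.out = 300)
  membrane_motion(xs, V0 * exp(-((xs - 0.8e-3) / 0.3e-3)^2) *
                    exp(-1i * 2 * pi * xs / 0.5e-3), 2 * pi * f)
}

small_field <- function() fx("small_field", function()
  solve_oscillatory(small_geom(), std_fluid(), gauss_motion(),
                    op = small_op()))

# an oscillatory_field-shaped object holding analytic phasors on a grid,
# sufficient for stokes_drift() / reynolds_forcing()
synthetic_field <- function(geom, fu, fv, omega, fluid = std_fluid()) {
  bc <- function(f) function(x, y) rep_len(f(x, y), length(x)) # broadcast
  u <- outer(geom$xf, geom$yc, bc(fu))
  v <- outer(geom$xc, geom$yf, bc(fv))
  structure(list(geom = geom, fluid = fluid, omega = omega, u = u, v = v),
            class = "oscillatory_field")
}

# plain rectangular-ish geometry (helicotrema irrelevant) for analytic fields
plain_geom <- function() fx("plain_geom", function()
  cochlea_geometry(L = 2e-3, h = 0.3e-3, helicotrema_len = 0.4e-3,
                   dx = 25e-6, dy_min = 10e-6, dy_max = 15e-6,
                   growth = 1.1, f_max = 1e3))

# brute-force Lagrangian drift: integrate a tracer through the analytic
# time-dependent velocity (RK4), return net displacement rate over full
# cycles after a transient cycle
brute_drift <- function(u_fun, v_fun, omega, x0, y0,
                        n_per_cycle = 2048L, n_cycles = 4L) {
  dt <- 2 * pi / omega / n_per_cycle
  x <- x0; y <- y0
  pos_at_cycle <- matrix(NA_real_, n_cycles + 1L, 2L)
  pos_at_cycle[1L, ] <- c(x, y)
  vel <- function(x, y, t) c(u_fun(x, y, t), v_fun(x, y, t))
  for (c in seq_len(n_cycles)) {
    for (s in seq_len(n_per_cycle)) {
      t0 <- ((c - 1L) * n_per_cycle + (s - 1L)) * dt
      k1 <- vel(x, y, t0)
      k2 <- vel(x + dt / 2 * k1[1], y + dt / 2 * k1[2], t0 + dt / 2)
      k3 <- vel(x + dt / 2 * k2[1], y + dt / 2 * k2[2], t0 + dt / 2)
      k4 <- vel(x + dt * k3[1], y + dt * k3[2], t0 + dt)
      x <- x + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
      y <- y + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    }
    pos_at_cycle[c + 1L, ] <- c(x, y)
  }
  T <- 2 * pi / omega
  (pos_at_cycle[n_cycles + 1L, ] - pos_at_cycle[2L, ]) / ((n_cycles - 1L) * T)
}

# cell-centred max Lagrangian speed of a streaming field
max_streaming_speed <- function(sf, x_range = NULL) {
  g <- sf$geom
  sp <- sqrt(otostream:::u_at_cc(g, sf$u_ss)^2 +
               otostream:::v_at_cc(g, sf$v_ss)^2)
  if (!is.null(x_range)) sp <- sp[g$xc >= x_range[1] & g$xc <= x_range[2], ]
  max(sp)
}

# validation-scale oracle configuration (thicker model fluid so the mean
# flow establishes within a cycle; 50 Hz Gaussian travelling wave)
oracle_config <- function(V0 = 2.5e-3) {
  fl <- fluid_properties(rho0 = 1000, nu = 1e-4)
  geom <- fx("oracle_geom", function()
    cochlea_geometry(L = 4e-3, h = 0.8e-3, helicotrema_len = 0.8e-3,
                     dx = 66e-6, dy_max = 40e-6, f_max = 50, fluid = fl))
  xs <- seq(0, geom$L, length.out = 400)
  mot <- membrane_motion(xs, V0 * exp(-((xs - 1.5e-3) / 0.5e-3)^2) *
                           exp(-1i * 2 * pi * xs / 2e-3), 2 * pi * 50)
  probes <- expand.grid(x = c(1.0e-3, 1.5e-3, 2.0e-3),
                        y = c(-0.4e-3, -0.2e-3, 0.25e-3))
  list(fluid = fl, geom = geom, motion = mot, probes = probes)
}

# comb streaming field at test resolution, shared between comb tests
comb_fixture <- function() fx("comb_sf", function() {
  props <- std_props()
  comb <- comb_from_delta(tonotopic_map(props), n = 10, delta = 330e-6,
                          spl = 80)
  geom <- cochlea_geometry(L = 7e-3, dx = 50e-6, f_max = max(comb$f),
                           growth = 1.3)
  list(comb = comb, geom = geom,
       sf = solve_streaming(comb, props, geom, std_fluid()))
})
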