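# Finite-mass particle transport: drag relaxation, collisions, seeding,
# passive-tracer limit, transport-time quadrature

test_that("particles stay put in still fluid and relax to a uniform flow", {
  geom <- small_geom(); fl <- std_fluid()
  props <- particle_properties(count = 4)
  ens <- seed_particles(geom, props, region = c(0.2e-3, 0.6e-3))
  still <- step_particles(ens, function(x, y, t) cbind(0 * x, 0 * x),
                          geom, fl, dt = 1e-3, T = 0.1)
  expect_equal(still$x, ens$x)
  expect_equal(still$y, ens$y)

  # uniform flow U: displacement after T >> tau_p equals U T to 1e-6
  U <- 50e-6; T <- 0.02
  adv <- step_particles(ens, function(x, y, t) cbind(rep(U, length(x)), 0 * x),
                        geom, fl, dt = 1e-4, T = T)
  expect_equal(adv$x, ens$x + U * T, tolerance = 1e-6)
  expect_equal(adv$vx, rep(U, nrow(ens)), tolerance = 1e-9)
  # drag relaxation time for 200 nm neutrally buoyant spheres ~ 2.2 ns
  expect_equal(otostream:::particle_tau(props, fl), 2.22e-9, tolerance = 0.01)
})

test_that("wall impacts rebound with the restitution coefficient", {
  geom <- small_geom(); fl <- std_fluid()
  props <- particle_properties(count = 1, restitution = 0.95, friction = 1e-3)
  ens <- seed_particles(geom, props, region = c(0.9e-3, 1.1e-3))
  ens$y <- geom$h - 1e-9 # just below the top wall
  # carrier flow pushing to the wall; particle follows it and reflects
  w <- 1e-3
  hit <- step_particles(ens, function(x, y, t) cbind(0 * x, rep(w, length(x))),
                        geom, fl, dt = 1e-5, T = 2e-5)
  expect_lt(hit$y, geom$h)
  # velocity right after the bounce: -0.95 w vertically (before re-relaxing)
  one <- step_particles(ens, function(x, y, t) cbind(0 * x, rep(w, length(x))),
                        geom, fl, dt = 2e-6, T = 2e-6)
  expect_equal(one$vy, -0.95 * w, tolerance = 1e-6)
  expect_equal(abs(one$vx), 0)

  # membrane acts as an internal wall: a particle pushed across y = 0 in the
  # membrane region is reflected back into its chamber
  ens2 <- seed_particles(geom, props, region = c(0.5e-3, 0.7e-3))
  ens2$y <- 1e-6
  down <- step_particles(ens2, function(x, y, t) cbind(0 * x, rep(-w, length(x))),
                         geom, fl, dt = 1e-5, T = 1e-5)
  expect_gt(down$y, 0)
})

test_that("seeding is deterministic, grid-uniform and split across chambers", {
  geom <- small_geom()
  props <- particle_properties(count = 500)
  a <- seed_particles(geom, props, seed = 3L, jitter = 0.5)
  b <- seed_particles(geom, props, seed = 3L, jitter = 0.5)
  expect_identical(a, b)
  expect_equal(nrow(a), 500)
  expect_equal(sum(a$y > 0), 250)
  expect_equal(sum(a$y < 0), 250)
  expect_true(all(a$vx == 0 & a$vy == 0))
  expect_true(all(abs(a$y) <= geom$h & a$x >= 0 & a$x <= geom$L))
  # single particle sits at the region centre
  one <- seed_particles(geom, particle_properties(count = 1),
                        region = c(0.2e-3, 0.4e-3), margin = 0)
  expect_equal(one$x[1], 0.3e-3, tolerance = 0.2)
})

test_that("200 nm particles are near-perfect tracers over 100 cycles", {
  geom <- small_geom(); fl <- std_fluid()
  omega <- 2 * pi * 20e3
  k <- 5e3; U <- 1e-3
  flow <- function(x, y, t) cbind(U * cos(omega * t - k * x),
                                  0.2 * U * sin(omega * t - k * x))
  props <- particle_properties(count = 1)
  mk <- function(d) {
    e <- seed_particles(geom, particle_properties(count = 1, diameter = d),
                        region = c(0.9e-3, 1.1e-3))
    e$y <- 0.15e-3
    e
  }
  T <- 100 * 2 * pi / omega
  dt <- 2 * pi / omega / 40
  fin <- step_particles(mk(200e-9), flow, geom, fl, dt = dt, T = T,
                        period = 2 * pi / omega)
  # passive tracer: tau -> 0 via a vanishing diameter
  pas <- step_particles(mk(1e-12), flow, geom, fl, dt = dt, T = T,
                        period = 2 * pi / omega)
  path_scale <- U / omega * 100 # ~ cumulative oscillatory path
  dev <- sqrt((fin$x - pas$x)^2 + (fin$y - pas$y)^2)
  expect_lt(dev / path_scale, 1e-3)
  # time-step guard
  expect_error(step_particles(mk(200e-9), flow, geom, fl,
                              dt = 2 * pi / omega / 5, T = T,
                              period = 2 * pi / omega), "10 steps")
})

test_that("ensemble statistics are order-independent and reproducible", {
  geom <- small_geom(); fl <- std_fluid()
  props <- particle_properties(count = 40)
  ens <- seed_particles(geom, props, seed = 9L, jitter = 0.3)
  flow <- function(x, y, t) cbind(1e-4 * sin(2 * pi * y / geom$h),
                                  5e-5 * cos(2 * pi * x / geom$L))
  adv <- step_particles(ens, flow, geom, fl, dt = 1e-3, T = 0.05)
  perm <- sample.int(nrow(ens))
  ens_p <- ens[perm, ]
  adv_p <- step_particles(ens_p, flow, geom, fl, dt = 1e-3, T = 0.05)
  expect_identical(adv$x[perm], adv_p$x)
  expect_identical(adv$y[perm], adv_p$y)
  # bit-reproducible rerun
  expect_identical(adv, step_particles(ens, flow, geom, fl, dt = 1e-3, T = 0.05))
})

test_that("transport time integrates the inverse lane speed", {
  geom <- small_geom()
  mk_sf <- function(u_fun) {
    ucc <- outer(c(geom$xf), geom$yc, function(x, y) u_fun(x))
    vss <- matrix(0, geom$Nx, geom$Ny + 1)
    structure(list(geom = geom, u_ss = ucc, v_ss = vss,
                   provenance = tibble::tibble(f = 1)),
              class = "streaming_field")
  }
  # uniform u_ss = U: t = L / U  (2 um/s over 1 mm -> 500 s; the printed
  # arithmetic: 2 um/s over 2.75 mm is 1375 s)
  sf_u <- mk_sf(function(x) rep(2e-6, length(x)))
  tt <- transport_time(sf_u, 0.5e-3, 1.5e-3)
  expect_equal(tt$time, 1e-3 / 2e-6, tolerance = 0.01)
  expect_equal(2.75e-3 / 2e-6, 1375)

  # linear profile u = a x: t = ln(x2/x1)/a
  a <- 5e-3
  sf_l <- mk_sf(function(x) a * x)
  tt2 <- transport_time(sf_l, 0.5e-3, 1.5e-3)
  expect_equal(tt2$time, log(3) / a, tolerance = 0.01)

  # reversed flow: unreachable, with the blocking station reported
  sf_r <- mk_sf(function(x) ifelse(x < 1e-3, 2e-6, -1e-6))
  tt3 <- transport_time(sf_r, 0.5e-3, 1.5e-3)
  expect_false(tt3$reachable)
  expect_equal(tt3$blocking_x, 1e-3, tolerance = 0.05)
  expect_equal(tt3$time, Inf)
})
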