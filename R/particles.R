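#' Drug-particle properties
#'
#' Finite-mass, neutrally buoyant tracer particles representing drug
#' carriers in suspension: 200 nm diameter, density of the fluid, an almost
#' elastic wall-collision model (restitution 0.95) and a small tangential
#' collision friction (10^-3).  The Stokes drag relaxation time
#' \eqn{\tau_p = \rho_p d^2/(18\rho_0\nu)} is about 2.2 ns, so the Stokes
#' number \eqn{\omega\tau_p} is far below one even at 20 kHz and the
#' particles follow the flow almost passively.
#'
#' @param diameter Particle diameter (m).
#' @param density Particle density (kg/m^3).
#' @param restitution Normal velocity restitution coefficient on impact,
#'   in \[0, 1\].
#' @param friction Tangential velocity loss fraction on impact (the
#'   collision friction coefficient).
#' @param count Number of particles.
#' @return An object of class `particle_properties`.
#' @export
particle_properties <- function(diameter = 200e-9, density = 1000,
                                restitution = 0.95, friction = 1e-3,
                                count = 5000L) {
  stopifnot(diameter > 0, density > 0, restitution >= 0, restitution <= 1,
            friction >= 0, friction <= 1, count >= 1)
  structure(list(diameter = diameter, density = density,
                 restitution = restitution, friction = friction,
                 count = as.integer(count)),
            class = "particle_properties")
}

# drag relaxation time (s)
particle_tau <- function(props, fluid)
  props$density * props$diameter^2 / (18 * fluid$rho0 * fluid$nu)

#' Seed a particle ensemble in the basal region
#'
#' Particles are laid out on a uniform grid covering `region` in each
#' chamber (half the count per chamber), at rest.  Deterministic given
#' `seed`; optional uniform jitter of up to half a grid spacing.
#'
#' @param geom A [cochlea_geometry()].
#' @param props A [particle_properties()].
#' @param region `c(x0, x1)` longitudinal extent (m) of the seeded block;
#'   default the basal fifth of the membrane-covered region.
#' @param margin Clearance kept from walls and membrane (m).
#' @param seed Integer seed (used only when `jitter > 0`).
#' @param jitter Jitter amplitude as a fraction of the seeding grid spacing.
#' @return A tibble of class `particle_ensemble` with columns `id`, `x`,
#'   `y`, `vx`, `vy`; attributes `props` and `seed`.
#' @export
seed_particles <- function(geom, props = particle_properties(),
                           region = NULL, margin = 10e-6, seed = 1L,
                           jitter = 0) {
  if (is.null(region)) region <- c(0, 0.2 * geom$Lm)
  stopifnot(region[1] >= 0, region[2] <= geom$L, region[2] > region[1])
  n_ch <- ceiling(props$count / 2)
  aspect <- (region[2] - region[1]) / (geom$h - 2 * margin)
  nx <- max(1L, round(sqrt(n_ch * aspect)))
  ny <- max(1L, ceiling(n_ch / nx))
  # cell-centred layout keeps particles off the walls and the membrane
  xs <- region[1] + margin +
    (seq_len(nx) - 0.5) / nx * (region[2] - region[1] - 2 * margin)
  ys <- margin + (seq_len(ny) - 0.5) / ny * (geom$h - 2 * margin)
  gpts <- expand.grid(x = xs, y = ys)[seq_len(n_ch), ]
  pts <- rbind(cbind(gpts$x, gpts$y), cbind(gpts$x, -gpts$y))
  pts <- pts[seq_len(props$count), , drop = FALSE] # odd counts favour upper
  if (jitter > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
    dx <- if (nx > 1) diff(xs[1:2]) else margin
    dy <- if (ny > 1) diff(ys[1:2]) else margin
    pts[, 1] <- pts[, 1] + runif(nrow(pts), -jitter * dx / 2, jitter * dx / 2)
    pts[, 2] <- pts[, 2] + runif(nrow(pts), -jitter * dy / 2, jitter * dy / 2)
  }
  out <- tibble(id = seq_len(nrow(pts)), x = pts[, 1], y = pts[, 2],
                vx = 0, vy = 0)
  class(out) <- c("particle_ensemble", class(out))
  attr(out, "props") <- props
  attr(out, "seed") <- seed
  out
}

# bilinear sampler for a staggered velocity pair; returns function(x, y)
# giving a two-column matrix of (u, v) at the query points
flow_sampler <- function(geom, u, v) {
  xf <- geom$xf; xc <- geom$xc; yc <- geom$yc; yf <- geom$yf
  interp2 <- function(gx, gy, M, x, y) {
    ix <- pmin(pmax(findInterval(x, gx), 1L), length(gx) - 1L)
    iy <- pmin(pmax(findInterval(y, gy), 1L), length(gy) - 1L)
    tx <- pmin(pmax((x - gx[ix]) / (gx[ix + 1L] - gx[ix]), 0), 1)
    ty <- pmin(pmax((y - gy[iy]) / (gy[iy + 1L] - gy[iy]), 0), 1)
    M[cbind(ix, iy)] * (1 - tx) * (1 - ty) +
      M[cbind(ix + 1L, iy)] * tx * (1 - ty) +
      M[cbind(ix, iy + 1L)] * (1 - tx) * ty +
      M[cbind(ix + 1L, iy + 1L)] * tx * ty
  }
  function(x, y) cbind(interp2(xf, yc, u, x, y), interp2(xc, yf, v, x, y))
}

#' Advance finite-mass particles through a (possibly time-dependent) flow
#'
#' Integrates \eqn{m_p \dot v = 3\pi\mu d (u - v)}, \eqn{\dot x = v}
#' (Stokes drag, \eqn{\mu = \rho_0\nu}).  Because the drag relaxation time
#' (ns) is vastly shorter than any flow time step, the linear drag is
#' integrated exactly over each step (exponential integrator), with the
#' fluid velocity sampled at the particle's midpoint position (second
#' order); the passive-tracer limit is recovered exactly when
#' \eqn{dt \gg \tau_p}.  Wall and membrane impacts reflect the normal
#' velocity with factor `-restitution` and scale the tangential velocity by
#' `1 - friction`.
#'
#' @param ensemble A `particle_ensemble` from [seed_particles()].
#' @param flow Either a function `(x, y, t)` returning a 2-column matrix of
#'   fluid velocity (m/s), or a `streaming_field` (steady mean-flow
#'   advection).
#' @param geom A [cochlea_geometry()].
#' @param fluid A [fluid_properties()].
#' @param dt Time step (s); must resolve the fastest oscillation present
#'   (at least 10 steps per cycle, checked against `period` if given).
#' @param T Total integration time (s).
#' @param period Shortest oscillation period in the flow (s), if any, for
#'   the time-step check.
#' @param sample_every Record trajectory snapshots every this many steps
#'   (0 = none).
#' @return The advanced `particle_ensemble`; if sampling is on, attribute
#'   `trajectories` holds a tibble (id, t, x, y).
#' @export
step_particles <- function(ensemble, flow, geom, fluid = fluid_properties(),
                           dt, T, period = NULL, sample_every = 0L) {
  props <- attr(ensemble, "props") %||% particle_properties()
  if (inherits(flow, "streaming_field")) {
    smp <- flow_sampler(flow$geom, flow$u_ss, flow$v_ss)
    flow_fun <- function(x, y, t) smp(x, y)
  } else flow_fun <- flow
  if (!is.null(period) && dt > period / 10)
    abort("`dt` must give at least 10 steps per oscillation cycle")
  nstep <- ceiling(T / dt)
  tau <- particle_tau(props, fluid)
  x <- ensemble$x; y <- ensemble$y; vx <- ensemble$vx; vy <- ensemble$vy
  e <- props$restitution; tf <- 1 - props$friction
  traj <- list()
  decay <- exp(-dt / tau)
  # exact relaxation over dt towards the (frozen) local fluid velocity:
  #   v(t+dt) = u + (v - u) e^{-dt/tau}
  #   x(t+dt) = x + u dt + (v - u) tau (1 - e^{-dt/tau})
  for (s in seq_len(nstep)) {
    t0 <- (s - 1) * dt
    u1 <- flow_fun(x, y, t0)
    xm <- x + (vx * 0.5 + u1[, 1] * 0.5) * dt / 2 # midpoint predictor
    ym <- y + (vy * 0.5 + u1[, 2] * 0.5) * dt / 2
    um <- flow_fun(xm, ym, t0 + dt / 2)
    x_new <- x + um[, 1] * dt + (vx - um[, 1]) * tau * (1 - decay)
    y_new <- y + um[, 2] * dt + (vy - um[, 2]) * tau * (1 - decay)
    vx <- um[, 1] + (vx - um[, 1]) * decay
    vy <- um[, 2] + (vy - um[, 2]) * decay

    # membrane crossing detection before the outer walls
    crossed <- (sign(y_new) != sign(y)) & (pmin(x, x_new) < geom$Lm) &
      (y != 0)
    if (any(crossed)) {
      y_new[crossed] <- -y_new[crossed] # reflect about y = 0
      vy[crossed] <- -e * vy[crossed]
      vx[crossed] <- tf * vx[crossed]
    }
    m <- x_new < 0
    if (any(m)) { x_new[m] <- -x_new[m]; vx[m] <- -e * vx[m]; vy[m] <- tf * vy[m] }
    m <- x_new > geom$L
    if (any(m)) { x_new[m] <- 2 * geom$L - x_new[m]; vx[m] <- -e * vx[m]
                  vy[m] <- tf * vy[m] }
    m <- y_new > geom$h
    if (any(m)) { y_new[m] <- 2 * geom$h - y_new[m]; vy[m] <- -e * vy[m]
                  vx[m] <- tf * vx[m] }
    m <- y_new < -geom$h
    if (any(m)) { y_new[m] <- -2 * geom$h - y_new[m]; vy[m] <- -e * vy[m]
                  vx[m] <- tf * vx[m] }
    x <- x_new; y <- y_new
    if (sample_every > 0L && (s %% sample_every == 0L || s == nstep))
      traj[[length(traj) + 1L]] <-
        tibble(id = ensemble$id, t = s * dt, x = x, y = y)
  }
  out <- ensemble
  out$x <- x; out$y <- y; out$vx <- vx; out$vy <- vy
  if (length(traj)) attr(out, "trajectories") <- bind_rows(traj)
  out
}

#' Advect particles in the Lagrangian mean flow
#'
#' Fast transport mode: the oscillatory motion is already time-averaged into
#' the Lagrangian mean (`u_ss`, `v_ss`), so particles are advected in the
#' steady streaming field only.  Equivalent to [step_particles()] with the
#' full oscillatory flow up to corrections of order of the Stokes number.
#'
#' @inheritParams step_particles
#' @param streaming A `streaming_field`.
#' @param dt Time step (s); default limits displacement per step to a
#'   quarter cell at the largest streaming speed.
#' @export
mean_flow_advect <- function(ensemble, streaming, geom = streaming$geom,
                             fluid = fluid_properties(), T, dt = NULL,
                             sample_every = 0L) {
  if (is.null(dt)) {
    # cap the displacement per step at half a longitudinal cell; the
    # streaming field is smooth on the cell scale, so finer vertical cells
    # near the membrane do not constrain the step
    vmax <- max(max(abs(streaming$u_ss)), max(abs(streaming$v_ss)),
                .Machine$double.eps)
    dt <- min(0.5 * geom$dx / vmax, T / 100)
  }
  step_particles(ensemble, streaming, geom, fluid, dt = dt, T = T,
                 sample_every = sample_every)
}

#' Predicted transport time along the streaming channel
#'
#' Integrates \eqn{t = \int dx / u_{ss}(x, y_{lane}(x))} from `x_start` to
#' `x_end` along the near-membrane streaming channel, where
#' \eqn{y_{lane}(x)} follows the height of the strongest apex-ward flow at
#' each station (or a fixed `y_lane` if given).  If the lane crosses a
#' stagnation or reversal point the target is unreachable and the blocking
#' position is reported.
#'
#' @param streaming A `streaming_field`.
#' @param x_start,x_end Longitudinal interval (m), `x_end > x_start`.
#' @param y_lane Fixed lane height (m, signed); `NULL` (default) follows the
#'   per-column maximum of apex-ward `u_ss` in `chamber`.
#' @param chamber `"lower"` or `"upper"` (used when `y_lane` is `NULL`).
#' @return A one-row tibble: `time` (s; `Inf` if unreachable), `reachable`,
#'   `blocking_x` (NA if reachable), `mean_speed` (m/s).
#' @export
transport_time <- function(streaming, x_start, x_end, y_lane = NULL,
                           chamber = c("lower", "upper")) {
  chamber <- match.arg(chamber)
  geom <- streaming$geom
  stopifnot(x_end > x_start, x_start >= 0, x_end <= geom$L)
  ucc <- u_at_cc(geom, streaming$u_ss)
  jj <- if (chamber == "lower") which(geom$yc < 0) else which(geom$yc > 0)
  cols <- which(geom$xc >= x_start & geom$xc <= x_end)
  if (!length(cols)) abort("interval contains no grid column")
  u_lane <- vapply(cols, function(i) {
    if (!is.null(y_lane)) {
      j <- jj[which.min(abs(geom$yc[jj] - y_lane))]
      ucc[i, j]
    } else max(ucc[i, jj])
  }, numeric(1))
  if (any(u_lane <= 0)) {
    bx <- geom$xc[cols[which(u_lane <= 0)[1]]]
    return(tibble(time = Inf, reachable = FALSE, blocking_x = bx,
                  mean_speed = NA_real_))
  }
  # extend the quadrature to the exact endpoints (constant extrapolation of
  # the lane speed over the end half-cells)
  xq <- c(x_start, geom$xc[cols], x_end)
  uq <- c(u_lane[1], u_lane, u_lane[length(u_lane)])
  tt <- pracma::trapz(xq, 1 / uq)
  tibble(time = tt, reachable = TRUE, blocking_x = NA_real_,
         mean_speed = (x_end - x_start) / tt)
}

#' @method autoplot particle_ensemble
#' @export
autoplot.particle_ensemble <- function(object, ...) {
  tr <- attr(object, "trajectories")
  if (is.null(tr)) {
    ggplot2::ggplot(object, ggplot2::aes(.data$x * 1e3, .data$y * 1e3)) +
      ggplot2::geom_point(size = 0.3, alpha = 0.5) +
      ggplot2::labs(x = "x (mm)", y = "y (mm)", title = "Particle positions")
  } else {
    ggplot2::ggplot(tr, ggplot2::aes(.data$x * 1e3, .data$y * 1e3,
                                     group = .data$id, colour = .data$t)) +
      ggplot2::geom_path(alpha = 0.4) +
      ggplot2::scale_colour_viridis_c(name = "t (s)") +
      ggplot2::labs(x = "x (mm)", y = "y (mm)", title = "Particle trajectories")
  }
}
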