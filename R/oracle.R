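#' Settings for the time-domain oracle solver
#'
#' @param steps_per_cycle Time steps per cycle of the highest driving
#'   frequency (at least 10).
#' @param n_cycles Total number of cycles to integrate.
#' @param transient_cycles Cycles discarded before drift averaging.
#' @param courant_cap Upper bound on the realized Courant number
#'   \eqn{C_0 = u_{max}\Delta t/\Delta x} (must stay below 1).
#' @param theta Time-integration weight for the viscous term: 0.5 gives
#'   Crank-Nicolson (default), 1 the implicit Euler scheme typical of
#'   first-order transient solvers.
#' @return An object of class `oracle_settings`.
#' @export
oracle_settings <- function(steps_per_cycle = 64L, n_cycles = 12L,
                            transient_cycles = 5L, courant_cap = 0.9,
                            theta = 0.5) {
  stopifnot(steps_per_cycle >= 10L, n_cycles > transient_cycles,
            courant_cap > 0, courant_cap < 1, theta >= 0.5, theta <= 1)
  structure(list(steps_per_cycle = as.integer(steps_per_cycle),
                 n_cycles = as.integer(n_cycles),
                 transient_cycles = max(1L, as.integer(transient_cycles)),
                 courant_cap = courant_cap, theta = theta),
            class = "oracle_settings")
}

#' Time-domain Navier-Stokes oracle with tracer drift extraction
#'
#' A small, deliberately independent time-domain solver used only to
#' validate the frequency-domain pipeline: it integrates the incompressible
#' Navier-Stokes equations (explicit second-order Adams-Bashforth advection,
#' theta-weighted viscous terms, incremental pressure projection on the same
#' staggered grid) with the membrane transpiration
#' \eqn{V(x,t) = \sum_j Re[\hat V_j(x) e^{i\omega_j t}]} prescribed on the
#' flat membrane line, tracks passive tracers through the resolved
#' oscillatory flow, and reports their per-cycle Lagrangian drift after a
#' transient.  Because the tracers feel the genuine time-dependent flow,
#' their drift contains Eulerian streaming and Stokes drift together and is
#' compared against the `u_ss` of [solve_streaming_single()] with
#' `include_slip = FALSE` (the oracle's membrane is flat, so the
#' moving-boundary slip is the one term it cannot see).
#'
#' @param geom A coarse [cochlea_geometry()] (about 10^3-10^4 cells).
#' @param fluid A [fluid_properties()].
#' @param motions A [membrane_motion()] or list of them (distinct
#'   frequencies).
#' @param settings An [oracle_settings()].
#' @param probes A data frame or matrix with columns/cols `x`, `y` of probe
#'   positions where tracers are released.
#' @return A list of class `oracle_result`: `drift` (tibble: probe id, x,
#'   y, `u_drift`, `v_drift` in m/s averaged over the post-transient
#'   cycles), `cycle_drift` (per-cycle drift velocities for convergence
#'   assessment), `courant` (realized Courant number), `dt`.
#' @export
run_oracle <- function(geom, fluid, motions, settings = oracle_settings(),
                       probes) {
  if (inherits(motions, "membrane_motion")) motions <- list(motions)
  stopifnot(length(motions) >= 1)
  if (geom$Nx * geom$Ny > 2e4)
    warn("oracle grid larger than intended; this will be slow")
  omegas <- vapply(motions, function(m) m$omega, numeric(1))
  if (anyDuplicated(signif(omegas, 12)))
    abort("oracle driving frequencies must be distinct")
  probes <- as.data.frame(probes)
  stopifnot(nrow(probes) >= 1, all(c("x", "y") %in% names(probes)))

  op <- assemble_stokes(geom, fluid)
  n_u <- op$n_u; n_v <- op$n_v; n_p <- op$n_p
  iu_id <- seq_len(n_u); iv_id <- n_u + seq_len(n_v)
  ip_id <- n_u + n_v + seq_len(n_p)
  th <- settings$theta

  omega_max <- max(omegas)
  period_min <- 2 * pi / omega_max
  dt <- period_min / settings$steps_per_cycle
  period_base <- 2 * pi / min(omegas)
  steps_total <- ceiling(settings$n_cycles * period_base / dt)
  steps_cycle_base <- round(period_base / dt)

  # operator blocks (kinematic pressure)
  A_uu <- op$A0[iu_id, iu_id]   # -nu * Lap_u
  A_vv <- op$A0[iv_id, iv_id]
  G_u <- op$A0[iu_id, ip_id]    # gradient to u rows
  G_v <- op$A0[iv_id, ip_id]
  D_u <- op$A0[ip_id, iu_id]    # divergence (with pinned row zeroed)
  D_v <- op$A0[ip_id, iv_id]
  Lm_u <- op$L_memv[iu_id, ]    # membrane lift into u rows (zero here)
  Lm_v <- op$L_memv[iv_id, ]
  Lm_p <- op$L_memv[ip_id, ]    # membrane flux into continuity rows

  I_u <- Matrix::Diagonal(n_u)
  I_v <- Matrix::Diagonal(n_v)
  H_u <- Matrix::lu((1 / dt) * I_u + th * A_uu)
  H_v <- Matrix::lu((1 / dt) * I_v + th * A_vv)
  # pressure Poisson: div(grad psi) with Neumann walls; pin the same cell
  Lp <- D_u %*% G_u + D_v %*% G_v
  pin_local <- op$pin - n_u - n_v
  Lp[pin_local, ] <- 0
  Lp[pin_local, pin_local] <- 1
  LUp <- Matrix::lu(Lp)

  mem_v_at <- function(t) {
    out <- rep(0, geom$Nx)
    for (m in motions)
      out <- out + Re(m$interp(geom$xc) * exp(1i * m$omega * t))
    out[!geom$mem_col] <- 0
    out
  }

  u <- rep(0, n_u); v <- rep(0, n_v); q <- rep(0, n_p)
  Nu_prev <- NULL; Nv_prev <- NULL
  px <- probes$x; py <- probes$y
  cycle_pos <- list()
  cmax <- 0
  full_uv <- function(u, v, mem_v) {
    z <- c(u, v, rep(0, n_p))
    s <- unpack_solution(op, z, mem_v = mem_v)
    list(u = s$u, v = s$v)
  }
  fields_prev <- full_uv(u, v, mem_v_at(0))

  for (s in seq_len(steps_total)) {
    t0 <- (s - 1) * dt; t1 <- s * dt
    bc1 <- mem_v_at(t1)

    # advection at t0 (AB2)
    C <- convective_products_real(geom, fields_prev$u, fields_prev$v)
    Nu <- C$Cu[2:geom$Nx, , drop = FALSE]
    Nv <- C$Cv[, 2:geom$Ny, drop = FALSE][!op$dir_v]
    Nu <- as.vector(Nu)
    if (is.null(Nu_prev)) { Nu_e <- Nu; Nv_e <- Nv }
    else { Nu_e <- 1.5 * Nu - 0.5 * Nu_prev; Nv_e <- 1.5 * Nv - 0.5 * Nv_prev }
    Nu_prev <- Nu; Nv_prev <- Nv

    bc0 <- mem_v_at(t0)
    rhs_u <- u / dt - as.numeric(G_u %*% q) - Nu_e -
      (1 - th) * as.numeric(A_uu %*% u) +
      (1 - th) * as.numeric(Lm_u %*% bc0) + th * as.numeric(Lm_u %*% bc1)
    rhs_v <- v / dt - as.numeric(G_v %*% q) - Nv_e -
      (1 - th) * as.numeric(A_vv %*% v) +
      (1 - th) * as.numeric(Lm_v %*% bc0) + th * as.numeric(Lm_v %*% bc1)
    u_star <- as.numeric(Matrix::solve(H_u, rhs_u))
    v_star <- as.numeric(Matrix::solve(H_v, rhs_v))

    # enforce D u - Lm_p bc = 0:  Lp psi = (D u* - Lm_p bc1)/dt,
    # then u = u* - dt grad(psi)
    rhs_p <- (as.numeric(D_u %*% u_star) + as.numeric(D_v %*% v_star) -
                as.numeric(Lm_p %*% bc1)) / dt
    rhs_p[pin_local] <- 0
    psi <- as.numeric(Matrix::solve(LUp, rhs_p))
    u <- u_star - dt * as.numeric(G_u %*% psi)
    v <- v_star - dt * as.numeric(G_v %*% psi)
    q <- q + psi

    fields <- full_uv(u, v, bc1)
    umax <- max(abs(fields$u), abs(fields$v))
    cmax <- max(cmax, umax * dt / min(geom$dx, min(geom$dyc)))
    if (cmax > settings$courant_cap)
      abort(sprintf("Courant number %.2f exceeds the cap %.2f",
                    cmax, settings$courant_cap))

    # tracer step: RK2 midpoint with linear time interpolation
    s0 <- flow_sampler(geom, fields_prev$u, fields_prev$v)
    s1 <- flow_sampler(geom, fields$u, fields$v)
    uv0 <- s0(px, py)
    pxm <- px + uv0[, 1] * dt / 2; pym <- py + uv0[, 2] * dt / 2
    uvm <- (s0(pxm, pym) + s1(pxm, pym)) / 2
    px <- px + uvm[, 1] * dt; py <- py + uvm[, 2] * dt
    fields_prev <- fields

    if (s %% steps_cycle_base == 0L)
      cycle_pos[[length(cycle_pos) + 1L]] <- cbind(px, py)
  }

  n_cyc <- length(cycle_pos)
  keep <- (settings$transient_cycles + 1L):n_cyc
  cyc <- lapply(seq_len(n_cyc - 1L), function(k)
    (cycle_pos[[k + 1L]] - cycle_pos[[k]]) / period_base)
  cycle_drift <- bind_rows(lapply(seq_along(cyc), function(k)
    tibble(cycle = k + 1L, probe = seq_along(px),
           u_drift = cyc[[k]][, 1], v_drift = cyc[[k]][, 2])))
  post <- keep[keep <= n_cyc] # cycle indices used for the average
  first <- cycle_pos[[min(post) - 1L]]
  last <- cycle_pos[[max(post)]]
  span <- (max(post) - min(post) + 1L) * period_base
  drift <- tibble(probe = seq_along(px),
                  x = probes$x, y = probes$y,
                  u_drift = (last[, 1] - first[, 1]) / span,
                  v_drift = (last[, 2] - first[, 2]) / span)
  structure(list(drift = drift, cycle_drift = cycle_drift,
                 courant = cmax, dt = dt,
                 settings = settings),
            class = "oracle_result")
}

# real-valued convective products (u . grad) u at staggered nodes
convective_products_real <- function(geom, u, v) {
  Cu <- u * ddx_u(geom, u) + v_at_u(geom, v) * ddy_u(geom, u)
  Cv <- u_at_v(geom, u) * ddx_v(geom, v) + v * ddy_v(geom, v)
  list(Cu = Cu, Cv = Cv)
}

#' @export
print.oracle_result <- function(x, ...) {
  cat(sprintf("<oracle_result> %d probes, Courant %.3f, dt = %.3g s\n",
              nrow(x$drift), x$courant, x$dt))
  print(x$drift)
  invisible(x)
}

#' Drift-convergence check for an oracle run
#'
#' Compares the mean drift over successive halves of the post-transient
#' cycles; a small relative change indicates the periodic state and the
#' drift estimate have converged.
#'
#' @param result An `oracle_result`.
#' @return A tibble with per-probe relative change between the two halves.
#' @export
oracle_convergence <- function(result) {
  tr <- result$settings$transient_cycles
  cd <- dplyr::filter(result$cycle_drift, .data$cycle > tr + 1L)
  cyc <- sort(unique(cd$cycle))
  h1 <- cyc[seq_len(floor(length(cyc) / 2))]
  agg <- function(cset) cd |>
    dplyr::filter(.data$cycle %in% cset) |>
    group_by(.data$probe) |>
    summarise(u = mean(.data$u_drift), v = mean(.data$v_drift),
              .groups = "drop")
  a <- agg(h1); b <- agg(setdiff(cyc, h1))
  tibble(probe = a$probe,
         rel_change = sqrt((a$u - b$u)^2 + (a$v - b$v)^2) /
           pmax(sqrt(b$u^2 + b$v^2), .Machine$double.eps))
}
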