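# Staggered-grid (MAC) discretization of the incompressible (unsteady)
# Stokes equations on the two-chamber domain.  One assembly serves three
# solvers: the frequency-domain oscillatory solve (A0 + i*omega*D), the
# steady streaming solve (A0), and the time-domain oracle (which reuses the
# viscous blocks, gradient, divergence and boundary-lift operators).
#
# Unknowns (kinematic pressure q = p/rho0):
#   u at interior vertical faces   (i = 1..Nx-1, j = 1..Ny)
#   v at interior horizontal faces (i = 1..Nx,  j = 1..Ny-1), excluding the
#     membrane face row (j = jm, mem_col) where v is a Dirichlet value
#   q at cell centres (i = 1..Nx, j = 1..Ny), one cell pinned
#
# Boundary data enter through three lift operators, so that
#   rhs = f  +  L_memv %*% mem_v  +  L_up %*% mem_u_up  +  L_dn %*% mem_u_dn
# where mem_v is the transpiration velocity on the membrane face row (per
# column), and mem_u_up / mem_u_dn are tangential wall velocities on the two
# sides of the membrane (per interior u-face) - zero for a no-slip membrane,
# the steady streaming slip for the mean-flow problem, or a prescribed
# oscillation for the flat-plate benchmark.

assemble_stokes <- function(geom, fluid) {
  Nx <- geom$Nx; Ny <- geom$Ny; Nxm1 <- Nx - 1L; jm <- geom$jm
  dx <- geom$dx; yc <- geom$yc; yf <- geom$yf; dyc <- geom$dyc
  nu <- fluid$nu
  mem_xf <- geom$mem_xf   # length Nx-1
  mem_col <- geom$mem_col # length Nx

  dir_v <- matrix(FALSE, Nx, Ny - 1L)
  dir_v[mem_col, jm] <- TRUE
  vmap <- matrix(0L, Nx, Ny - 1L)
  vmap[!dir_v] <- seq_len(sum(!dir_v))

  n_u <- Nxm1 * Ny
  n_v <- sum(!dir_v)
  n_p <- Nx * Ny
  N <- n_u + n_v + n_p

  iu <- function(i, j) (j - 1L) * Nxm1 + i
  iv <- function(i, j) n_u + vmap[cbind(i, j)]
  ip <- function(i, j) n_u + n_v + (j - 1L) * Nx + i

  ti <- vector("list", 64L); tj <- vector("list", 64L); tx <- vector("list", 64L)
  nt <- 0L
  add <- function(r, c, x) {
    keep <- x != 0
    nt <<- nt + 1L
    ti[[nt]] <<- r[keep]; tj[[nt]] <<- c[keep]; tx[[nt]] <<- x[keep]
  }
  # lift triplets: (row, bc-index, coef) per bc vector
  lm_r <- list(); lm_c <- list(); lm_x <- list()  # mem_v
  lu_r <- list(); lu_c <- list(); lu_x <- list()  # mem_u_up
  ld_r <- list(); ld_c <- list(); ld_x <- list()  # mem_u_dn
  add_lift <- function(store, r, c, x) {
    keep <- x != 0
    switch(store,
           mv = { lm_r[[length(lm_r) + 1L]] <<- r[keep]
                  lm_c[[length(lm_c) + 1L]] <<- c[keep]
                  lm_x[[length(lm_x) + 1L]] <<- x[keep] },
           up = { lu_r[[length(lu_r) + 1L]] <<- r[keep]
                  lu_c[[length(lu_c) + 1L]] <<- c[keep]
                  lu_x[[length(lu_x) + 1L]] <<- x[keep] },
           dn = { ld_r[[length(ld_r) + 1L]] <<- r[keep]
                  ld_c[[length(ld_c) + 1L]] <<- c[keep]
                  ld_x[[length(ld_x) + 1L]] <<- x[keep] })
  }

  ## ---- u momentum ----
  ii <- rep(seq_len(Nxm1), Ny)
  jj <- rep(seq_len(Ny), each = Nxm1)
  row <- iu(ii, jj)
  diag_u <- numeric(n_u)

  cx <- nu / dx^2
  left_ok <- ii > 1L
  add(row[left_ok], iu(ii[left_ok] - 1L, jj[left_ok]), rep(-cx, sum(left_ok)))
  right_ok <- ii < Nxm1
  add(row[right_ok], iu(ii[right_ok] + 1L, jj[right_ok]), rep(-cx, sum(right_ok)))
  diag_u <- diag_u + 2 * cx  # boundary u = 0 keeps the full diagonal

  # y legs (finite volume): wall above/below may be outer wall or membrane
  at_mem <- mem_xf[ii]
  up_wall <- jj == Ny
  up_mem <- (jj == jm) & at_mem
  g_up <- ifelse(up_wall, yf[Ny + 1L] - yc[Ny],
                 ifelse(up_mem, -yc[jm], c(diff(yc), NA)[jj]))
  c_up <- nu / (dyc[jj] * g_up)
  diag_u <- diag_u + c_up
  int_up <- !up_wall & !up_mem
  add(row[int_up], iu(ii[int_up], jj[int_up] + 1L), -c_up[int_up])
  add_lift("dn", row[up_mem], ii[up_mem], c_up[up_mem])

  dn_wall <- jj == 1L
  dn_mem <- (jj == jm + 1L) & at_mem
  g_dn <- ifelse(dn_wall, yc[1L] - yf[1L],
                 ifelse(dn_mem, yc[jm + 1L], c(NA, diff(yc))[jj]))
  c_dn <- nu / (dyc[jj] * g_dn)
  diag_u <- diag_u + c_dn
  int_dn <- !dn_wall & !dn_mem
  add(row[int_dn], iu(ii[int_dn], jj[int_dn] - 1L), -c_dn[int_dn])
  add_lift("up", row[dn_mem], ii[dn_mem], c_dn[dn_mem])

  add(row, row, diag_u)
  # pressure gradient (kinematic): +(q[i+1,j] - q[i,j])/dx
  add(row, ip(ii + 1L, jj), rep(1 / dx, n_u))
  add(row, ip(ii, jj), rep(-1 / dx, n_u))

  ## ---- v momentum ----
  vidx <- which(!dir_v, arr.ind = TRUE)
  vi <- vidx[, 1L]; vj <- vidx[, 2L]
  vrow <- iv(vi, vj)
  diag_v <- numeric(n_v)

  # x legs: side walls at half spacing; neighbours may be membrane Dirichlet
  for (s in c(-1L, 1L)) {
    nb <- vi + s
    at_wall <- nb < 1L | nb > Nx
    cco <- ifelse(at_wall, nu / dx * (1 / (dx / 2)), cx)
    diag_v <- diag_v + cco
    inb <- !at_wall
    nb_dir <- logical(length(vi)); nb_dir[inb] <- dir_v[cbind(nb[inb], vj[inb])]
    int <- inb & !nb_dir
    add(vrow[int], iv(nb[int], vj[int]), -cco[int])
    lift <- inb & nb_dir
    add_lift("mv", vrow[lift], nb[lift], cco[lift])
  }

  # y legs
  hv <- (dyc[vj] + dyc[vj + 1L]) / 2
  for (s in c(-1L, 1L)) {
    nb <- vj + s
    at_wall <- nb < 1L | nb > (Ny - 1L)
    sp <- if (s == 1L) dyc[vj + 1L] else dyc[vj]
    cco <- nu / (hv * sp)
    diag_v <- diag_v + cco
    inb <- !at_wall
    nb_dir <- logical(length(vi)); nb_dir[inb] <- dir_v[cbind(vi[inb], nb[inb])]
    int <- inb & !nb_dir
    add(vrow[int], iv(vi[int], nb[int]), -cco[int])
    lift <- inb & nb_dir
    add_lift("mv", vrow[lift], vi[lift], cco[lift])
  }

  add(vrow, vrow, diag_v)
  gv <- diff(yc)[vj] # yc[j+1] - yc[j]
  add(vrow, ip(vi, vj + 1L), 1 / gv)
  add(vrow, ip(vi, vj), -1 / gv)

  ## ---- continuity ----
  ci <- rep(seq_len(Nx), Ny)
  cj <- rep(seq_len(Ny), each = Nx)
  crow <- ip(ci, cj)
  rf <- ci <= Nxm1 # right face interior
  add(crow[rf], iu(ci[rf], cj[rf]), rep(1 / dx, sum(rf)))
  lf <- ci >= 2L
  add(crow[lf], iu(ci[lf] - 1L, cj[lf]), rep(-1 / dx, sum(lf)))

  # top face (row cj), bottom face (row cj - 1)
  tf_int <- cj <= Ny - 1L
  tf_dir <- logical(length(ci))
  tf_dir[tf_int] <- dir_v[cbind(ci[tf_int], cj[tf_int])]
  tin <- tf_int & !tf_dir
  add(crow[tin], iv(ci[tin], cj[tin]), 1 / dyc[cj[tin]])
  add_lift("mv", crow[tf_int & tf_dir], ci[tf_int & tf_dir],
           -1 / dyc[cj[tf_int & tf_dir]])

  bf_int <- cj >= 2L
  bf_dir <- logical(length(ci))
  bf_dir[bf_int] <- dir_v[cbind(ci[bf_int], cj[bf_int] - 1L)]
  bin <- bf_int & !bf_dir
  add(crow[bin], iv(ci[bin], cj[bin] - 1L), -1 / dyc[cj[bin]])
  add_lift("mv", crow[bf_int & bf_dir], ci[bf_int & bf_dir],
           1 / dyc[cj[bf_int & bf_dir]])

  Ti <- unlist(ti[seq_len(nt)]); Tj <- unlist(tj[seq_len(nt)])
  Tx <- unlist(tx[seq_len(nt)])
  Lm_r <- unlist(lm_r); Lm_c <- unlist(lm_c); Lm_x <- unlist(lm_x)
  Lu_r <- unlist(lu_r); Lu_c <- unlist(lu_c); Lu_x <- unlist(lu_x)
  Ld_r <- unlist(ld_r); Ld_c <- unlist(ld_c); Ld_x <- unlist(ld_x)

  # pin the pressure in the top basal corner cell
  pin <- ip(1L, Ny)
  keep <- Ti != pin
  Ti <- c(Ti[keep], pin); Tj <- c(Tj[keep], pin); Tx <- c(Tx[keep], 1)
  keepL <- Lm_r != pin
  Lm_r <- Lm_r[keepL]; Lm_c <- Lm_c[keepL]; Lm_x <- Lm_x[keepL]

  A0 <- Matrix::sparseMatrix(i = Ti, j = Tj, x = Tx, dims = c(N, N))
  L_memv <- Matrix::sparseMatrix(i = Lm_r, j = Lm_c, x = Lm_x,
                                 dims = c(N, Nx))
  L_up <- Matrix::sparseMatrix(i = Lu_r, j = Lu_c, x = Lu_x,
                               dims = c(N, Nxm1))
  L_dn <- Matrix::sparseMatrix(i = Ld_r, j = Ld_c, x = Ld_x,
                               dims = c(N, Nxm1))

  list(geom = geom, fluid = fluid, A0 = A0,
       L_memv = L_memv, L_up = L_up, L_dn = L_dn,
       n_u = n_u, n_v = n_v, n_p = n_p, N = N, pin = pin,
       dir_v = dir_v, vmap = vmap)
}

# solve (A0 + i*omega*D) z = b with D = identity on velocity rows;
# real 2N x 2N augmented system (Matrix has no complex sparse solver)
solve_oscillatory_system <- function(op, omega, b) {
  N <- op$N; nuv <- op$n_u + op$n_v
  D <- Matrix::sparseMatrix(i = seq_len(nuv), j = seq_len(nuv),
                            x = rep(omega, nuv), dims = c(N, N))
  B <- rbind(cbind(op$A0, -D), cbind(D, op$A0))
  x <- Matrix::solve(B, c(Re(b), Im(b)))
  x <- as.numeric(x)
  x[seq_len(N)] + 1i * x[N + seq_len(N)]
}

# real sparse matrix times possibly-complex dense vector
spmv <- function(M, x) {
  if (is.complex(x))
    as.numeric(M %*% Re(x)) + 1i * as.numeric(M %*% Im(x))
  else as.numeric(M %*% x)
}

# rhs from boundary data and body force (kinematic units, m/s^2)
stokes_rhs <- function(op, mem_v = NULL, mem_u_up = NULL, mem_u_dn = NULL,
                       f_u = NULL, f_v = NULL) {
  geom <- op$geom
  b <- rep(0 + 0i, op$N)
  if (!is.null(f_u)) b[seq_len(op$n_u)] <- as.vector(f_u)
  if (!is.null(f_v)) b[op$n_u + seq_len(op$n_v)] <- f_v[!op$dir_v]
  if (!is.null(mem_v)) b <- b + spmv(op$L_memv, mem_v)
  if (!is.null(mem_u_up)) b <- b + spmv(op$L_up, mem_u_up)
  if (!is.null(mem_u_dn)) b <- b + spmv(op$L_dn, mem_u_dn)
  b
}

# unpack a solution vector into full staggered arrays (boundary faces filled)
unpack_solution <- function(op, z, mem_v = NULL) {
  geom <- op$geom
  Nx <- geom$Nx; Ny <- geom$Ny; jm <- geom$jm
  cplx <- is.complex(z)
  zero <- if (cplx) 0 + 0i else 0
  u <- matrix(zero, Nx + 1L, Ny)
  u[2:Nx, ] <- matrix(z[seq_len(op$n_u)], Nx - 1L, Ny)
  v <- matrix(zero, Nx, Ny + 1L)
  vin <- matrix(zero, Nx, Ny - 1L)
  vin[!op$dir_v] <- z[op$n_u + seq_len(op$n_v)]
  if (!is.null(mem_v)) vin[op$dir_v] <- mem_v[geom$mem_col]
  v[, 2:Ny] <- vin
  q <- matrix(z[op$n_u + op$n_v + seq_len(op$n_p)], Nx, Ny)
  list(u = u, v = v, p = q * op$fluid$rho0)
}

## ---- derivative / interpolation helpers on the staggered arrays ----
## u arrays are (Nx+1) x Ny at (xf, yc); v arrays are Nx x (Ny+1) at (xc, yf)

# second-order first derivative from three unevenly spaced points
d1_noneq <- function(y_dn, f_dn, y0, f0, y_up, f_up) {
  a <- y0 - y_dn; b <- y_up - y0
  (f_up * a^2 - f_dn * b^2 + f0 * (b^2 - a^2)) / (a * b * (a + b))
}

# d(u)/dx at interior u nodes -> (Nx+1) x Ny, boundary rows one-sided
ddx_u <- function(geom, u) {
  Nx <- geom$Nx; dx <- geom$dx
  out <- u * 0
  out[2:Nx, ] <- (u[3:(Nx + 1), ] - u[1:(Nx - 1), ]) / (2 * dx)
  out[1, ] <- (u[2, ] - u[1, ]) / dx
  out[Nx + 1, ] <- (u[Nx + 1, ] - u[Nx, ]) / dx
  out
}

# d(u)/dy at u nodes; honours outer walls and the membrane as data points
# mem_u_up/dn are tangential wall values on the membrane (default 0)
ddy_u <- function(geom, u, mem_u_up = NULL, mem_u_dn = NULL) {
  Nx <- geom$Nx; Ny <- geom$Ny; jm <- geom$jm
  yc <- geom$yc; yf <- geom$yf
  if (is.null(mem_u_up)) mem_u_up <- rep(0, Nx - 1L)
  if (is.null(mem_u_dn)) mem_u_dn <- rep(0, Nx - 1L)
  out <- u * 0
  for (j in seq_len(Ny)) {
    # default neighbours
    if (j == 1L) { y_dn <- yf[1]; f_dn <- u[, j] * 0 }
    else { y_dn <- yc[j - 1]; f_dn <- u[, j - 1] }
    if (j == Ny) { y_up <- yf[Ny + 1]; f_up <- u[, j] * 0 }
    else { y_up <- yc[j + 1]; f_up <- u[, j + 1] }
    d <- d1_noneq(y_dn, f_dn, yc[j], u[, j], y_up, f_up)
    # membrane-adjacent u rows: replace the across-membrane neighbour by the
    # wall value at y = 0 for walled columns
    if (j == jm) {
      w <- c(FALSE, geom$mem_xf, FALSE) # (Nx+1) faces; outer faces unwalled
      fw <- c(0, mem_u_dn, 0)
      dmem <- d1_noneq(yc[j - 1], u[, j - 1], yc[j], u[, j], 0, fw)
      d[w] <- dmem[w]
    }
    if (j == jm + 1L) {
      w <- c(FALSE, geom$mem_xf, FALSE)
      fw <- c(0, mem_u_up, 0)
      dmem <- d1_noneq(0, fw, yc[j], u[, j], yc[j + 1],
                       if (j == Ny) fw * 0 else u[, j + 1])
      if (j == Ny) dmem <- d1_noneq(0, fw, yc[j], u[, j], yf[Ny + 1], fw * 0)
      d[w] <- dmem[w]
    }
    out[, j] <- d
  }
  out
}

# v interpolated to u nodes -> (Nx+1) x Ny (midpoint average, exact in y)
v_at_u <- function(geom, v) {
  Nx <- geom$Nx; Ny <- geom$Ny
  out <- matrix(if (is.complex(v)) 0 + 0i else 0, Nx + 1L, Ny)
  vy <- (v[, 1:Ny] + v[, 2:(Ny + 1)]) / 2          # to cell centres, Nx x Ny
  out[2:Nx, ] <- (vy[1:(Nx - 1), ] + vy[2:Nx, ]) / 2
  out[1, ] <- vy[1, ]; out[Nx + 1, ] <- vy[Nx, ]
  out
}

# d(v)/dx at v nodes -> Nx x (Ny+1); side walls as data points at dx/2
ddx_v <- function(geom, v) {
  Nx <- geom$Nx; dx <- geom$dx
  out <- v * 0
  out[2:(Nx - 1), ] <- (v[3:Nx, ] - v[1:(Nx - 2), ]) / (2 * dx)
  zero <- v[1, ] * 0
  out[1, ] <- d1_noneq(-dx / 2, zero, 0, v[1, ], dx, v[2, ])
  out[Nx, ] <- d1_noneq(-dx, v[Nx - 1, ], 0, v[Nx, ], dx / 2, zero)
  out
}

# d(v)/dy at v nodes (face rows are unevenly spaced)
ddy_v <- function(geom, v) {
  Ny <- geom$Ny; yf <- geom$yf
  out <- v * 0
  for (j in 2:Ny)
    out[, j] <- d1_noneq(yf[j - 1], v[, j - 1], yf[j], v[, j],
                         yf[j + 1], v[, j + 1])
  out[, 1] <- (v[, 2] - v[, 1]) / (yf[2] - yf[1])
  out[, Ny + 1] <- (v[, Ny + 1] - v[, Ny]) / (yf[Ny + 1] - yf[Ny])
  out
}

# u interpolated to v nodes -> Nx x (Ny+1)
u_at_v <- function(geom, u) {
  Nx <- geom$Nx; Ny <- geom$Ny; yc <- geom$yc; yf <- geom$yf
  ux <- (u[1:Nx, ] + u[2:(Nx + 1), ]) / 2 # to cell centres, Nx x Ny
  out <- matrix(if (is.complex(u)) 0 + 0i else 0, Nx, Ny + 1L)
  for (j in 2:Ny) { # interior face rows: linear in y between yc[j-1], yc[j]
    t <- (yf[j] - yc[j - 1]) / (yc[j] - yc[j - 1])
    out[, j] <- (1 - t) * ux[, j - 1] + t * ux[, j]
  }
  out # wall rows stay zero (no-slip)
}

# cell-centred fields from staggered arrays
u_at_cc <- function(geom, u) (u[1:geom$Nx, ] + u[2:(geom$Nx + 1), ]) / 2
v_at_cc <- function(geom, v) (v[, 1:geom$Ny] + v[, 2:(geom$Ny + 1)]) / 2
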