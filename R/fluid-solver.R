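#' Pressure Poisson solve with homogeneous Neumann conditions
#'
#' Diagonalizes the cell-centered five-point Laplacian in the discrete
#' cosine basis in both directions (the transform-based solver the
#' projection step relies on). The right-hand side must have (numerically)
#' zero mean; the solution gauge is fixed by a zero-mean pressure.
#'
#' @param rhs Matrix (nx x ny) right-hand side.
#' @param grid An [eulerian_grid()].
#' @param ops Optional precomputed transform operators (internal use).
#' @param compat_tol Relative compatibility tolerance on `mean(rhs)`.
#' @return Matrix (nx x ny): zero-mean pressure with
#'   `laplacian(p) = rhs` to rounding.
#' @export
poisson_solve <- function(rhs, grid, ops = NULL, compat_tol = 1e-8) {
  if (is.null(ops)) ops <- dct_ops(grid)
  scale <- max(abs(rhs), 1e-300)
  if (abs(mean(rhs)) > compat_tol * scale) {
    stop("poisson_solve: incompatible right-hand side (nonzero mean ",
         format(mean(rhs)), " under pure Neumann conditions)", call. = FALSE)
  }
  rhat <- ops$Cx %*% rhs %*% ops$tCy
  rhat <- rhat / ops$lam
  rhat[1, 1] <- 0
  ops$tCx %*% rhat %*% ops$Cy
}

# orthonormal DCT-II matrix of size n
dct_matrix <- function(n) {
  k <- 0:(n - 1)
  i <- 0:(n - 1)
  C <- sqrt(2 / n) * cos(pi * outer(k, i + 0.5) / n)
  C[1, ] <- sqrt(1 / n)
  C
}

dct_ops <- function(grid) {
  Cx <- dct_matrix(grid$nx)
  Cy <- dct_matrix(grid$ny)
  lamx <- (2 * cos(pi * (0:(grid$nx - 1)) / grid$nx) - 2) / grid$h^2
  lamy <- (2 * cos(pi * (0:(grid$ny - 1)) / grid$ny) - 2) / grid$h^2
  lam <- outer(lamx, lamy, `+`)
  lam[1, 1] <- 1  # gauge mode, zeroed explicitly
  list(Cx = Cx, tCx = t(Cx), Cy = Cy, tCy = t(Cy), lam = lam)
}

# apply the Neumann five-point Laplacian (mirror ghosts) to a cell field
neumann_laplacian <- function(p, grid) {
  nx <- grid$nx; ny <- grid$ny
  pe <- rbind(p[1, ], p, p[nx, ])
  pe <- cbind(pe[, 1], pe, pe[, ny])
  (pe[1:nx, 2:(ny + 1)] + pe[3:(nx + 2), 2:(ny + 1)] +
      pe[2:(nx + 1), 1:ny] + pe[2:(nx + 1), 3:(ny + 2)] - 4 * p) / grid$h^2
}

#' Boundary conditions for one time level
#'
#' Velocity Dirichlet data on the four edges of the rectangle: the moving
#' reticular lamina at the bottom, the horizontally fixed but vertically
#' co-moving tectorial membrane at the top, and the analytic oscillatory
#' channel profile on the sides (vertical side velocity is zero, matching
#' the no-bundle analytic solution).
#'
#' @param grid An [eulerian_grid()].
#' @param u_bottom,u_top Scalar horizontal wall velocities.
#' @param v_wall Scalar vertical velocity shared by both walls.
#' @param u_left,u_right Horizontal side profiles (length ny), e.g. from
#'   [side_bc()].
#' @param v_side Scalar vertical side velocity (default 0).
#' @return A `wall_bc` list.
#' @export
wall_bc <- function(grid, u_bottom = 0, u_top = 0, v_wall = 0,
                    u_left = rep(0, grid$ny), u_right = u_left, v_side = 0) {
  list(u_bottom = u_bottom, u_top = u_top,
       v_bottom = v_wall, v_top = v_wall,
       u_left = u_left, u_right = u_right, v_side = v_side)
}

# Laplacian of u on interior faces (i = 2..nx), using Dirichlet side faces
# stored in the array and wall ghosts from bc
lap_u <- function(u, bc, grid) {
  nx <- grid$nx; ny <- grid$ny
  ug <- cbind(2 * bc$u_bottom - u[, 1], u, 2 * bc$u_top - u[, ny])
  (ug[1:(nx - 1), 2:(ny + 1)] + ug[3:(nx + 1), 2:(ny + 1)] +
      ug[2:nx, 1:ny] + ug[2:nx, 3:(ny + 2)] -
      4 * ug[2:nx, 2:(ny + 1)]) / grid$h^2
}

# Laplacian of v on interior faces (j = 2..ny), with side ghosts from bc
lap_v <- function(v, bc, grid) {
  nx <- grid$nx; ny <- grid$ny
  vg <- rbind(2 * bc$v_side - v[1, ], v, 2 * bc$v_side - v[nx, ])
  (vg[1:nx, 2:ny] + vg[3:(nx + 2), 2:ny] +
      vg[2:(nx + 1), 1:(ny - 1)] + vg[2:(nx + 1), 3:(ny + 1)] -
      4 * vg[2:(nx + 1), 2:ny]) / grid$h^2
}

# centered advection terms at interior faces
advect_u <- function(u, v, bc, grid) {
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  ug <- cbind(2 * bc$u_bottom - u[, 1], u, 2 * bc$u_top - u[, ny])
  ui <- ug[2:nx, 2:(ny + 1)]
  dudx <- (ug[3:(nx + 1), 2:(ny + 1)] - ug[1:(nx - 1), 2:(ny + 1)]) / (2 * h)
  dudy <- (ug[2:nx, 3:(ny + 2)] - ug[2:nx, 1:ny]) / (2 * h)
  vat <- (v[1:(nx - 1), 1:ny] + v[1:(nx - 1), 2:(ny + 1)] +
            v[2:nx, 1:ny] + v[2:nx, 2:(ny + 1)]) / 4
  ui * dudx + vat * dudy
}

advect_v <- function(u, v, bc, grid) {
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  vg <- rbind(2 * bc$v_side - v[1, ], v, 2 * bc$v_side - v[nx, ])
  vi <- vg[2:(nx + 1), 2:ny]
  dvdx <- (vg[3:(nx + 2), 2:ny] - vg[1:nx, 2:ny]) / (2 * h)
  dvdy <- (vg[2:(nx + 1), 3:(ny + 1)] - vg[2:(nx + 1), 1:(ny - 1)]) / (2 * h)
  uat <- (u[1:nx, 1:(ny - 1)] + u[1:nx, 2:ny] +
            u[2:(nx + 1), 1:(ny - 1)] + u[2:(nx + 1), 2:ny]) / 4
  uat * dvdx + vi * dvdy
}

# Dirichlet/ghost boundary contributions to the implicit Helmholtz RHS,
# per unit (nu * dt * theta) / h^2
bc_terms_u <- function(bc, grid) {
  nx <- grid$nx; ny <- grid$ny
  r <- matrix(0, nx - 1, ny)
  r[1, ] <- r[1, ] + bc$u_left
  r[nx - 1, ] <- r[nx - 1, ] + bc$u_right
  r[, 1] <- r[, 1] + 2 * bc$u_bottom
  r[, ny] <- r[, ny] + 2 * bc$u_top
  r
}

bc_terms_v <- function(bc, grid) {
  nx <- grid$nx; ny <- grid$ny
  r <- matrix(0, nx, ny - 1)
  r[, 1] <- r[, 1] + bc$v_bottom
  r[, ny - 1] <- r[, ny - 1] + bc$v_top
  r[1, ] <- r[1, ] + 2 * bc$v_side
  r[nx, ] <- r[nx, ] + 2 * bc$v_side
  r
}

# sparse Helmholtz operators (I - a L) for the two components
helmholtz_ops <- function(grid, a) {
  nx <- grid$nx; ny <- grid$ny; h2 <- grid$h^2
  tri <- function(n, end_mod) {
    d <- rep(-2, n)
    if (end_mod) d[c(1, n)] <- -3
    Matrix::bandSparse(n, k = c(-1, 0, 1),
                       diagonals = list(rep(1, n - 1), d, rep(1, n - 1))) / h2
  }
  Lu <- kronecker(Matrix::Diagonal(ny), tri(nx - 1, FALSE)) +
    kronecker(tri(ny, TRUE), Matrix::Diagonal(nx - 1))
  Lv <- kronecker(Matrix::Diagonal(ny - 1), tri(nx, TRUE)) +
    kronecker(tri(ny - 1, FALSE), Matrix::Diagonal(nx))
  Au <- Matrix::Diagonal((nx - 1) * ny) - a * Lu
  Av <- Matrix::Diagonal(nx * (ny - 1)) - a * Lv
  list(chol_u = Matrix::Cholesky(Matrix::forceSymmetric(Au)),
       chol_v = Matrix::Cholesky(Matrix::forceSymmetric(Av)))
}

#' Build a projection-method fluid solver
#'
#' Precomputes the Crank-Nicolson Helmholtz factorizations, the cosine
#' transforms of the pressure Poisson solver and the step closure. Advection
#' is explicit centered (Reynolds numbers here are far below 1; a `stokes`
#' switch drops it entirely); diffusion is implicit with weight `theta`
#' (0.5 = Crank-Nicolson), which is essential because the explicit diffusion
#' number `nu dt / h^2` is of order 100 at the paper-scale resolution and
#' time step.
#'
#' @param grid An [eulerian_grid()].
#' @param props A [fluid_props()].
#' @param dt Time step (s).
#' @param theta Implicitness of the viscous term (0.5 Crank-Nicolson,
#'   1 backward Euler).
#' @param stokes Drop the advection term.
#' @param div_tol Relative post-projection divergence tolerance (solver
#'   contract, checked every step).
#' @return A `fluid_solver` list of closures: `step(state, bc_old, bc_new,
#'   forcing)` and `force_response(fu, fv)` (the linear velocity response to
#'   a force density applied over one step, with homogeneous boundary data).
#' @export
fluid_solver <- function(grid, props, dt, theta = 0.5, stokes = FALSE,
                         div_tol = 1e-10) {
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  a1 <- theta * props$nu * dt
  a0 <- (1 - theta) * props$nu * dt
  ops <- helmholtz_ops(grid, a1)
  dops <- dct_ops(grid)
  rho <- props$rho

  solve_u <- function(rhs) {
    matrix(as.numeric(Matrix::solve(ops$chol_u, as.vector(rhs))), nx - 1, ny)
  }
  solve_v <- function(rhs) {
    matrix(as.numeric(Matrix::solve(ops$chol_v, as.vector(rhs))), nx, ny - 1)
  }

  project <- function(u, v) {
    dv <- divergence(u, v, grid)
    rhs <- (rho / dt) * dv
    rhs <- rhs - mean(rhs)
    p <- poisson_solve(rhs, grid, ops = dops, compat_tol = Inf)
    u[2:nx, ] <- u[2:nx, ] -
      (dt / rho) * (p[2:nx, ] - p[1:(nx - 1), ]) / h
    v[, 2:ny] <- v[, 2:ny] -
      (dt / rho) * (p[, 2:ny] - p[, 1:(ny - 1)]) / h
    res <- max(abs(neumann_laplacian(p, grid) - rhs))
    if (res > 1e-10 * max(abs(rhs), 1e-300)) {
      stop("fluid_solver: pressure Poisson residual ", format(res),
           " exceeds tolerance", call. = FALSE)
    }
    list(u = u, v = v, p = p)
  }

  step <- function(state, bc_old, bc_new, forcing = NULL) {
    u <- state$u; v <- state$v
    cfl <- max(abs(u), abs(v)) * dt / h
    if (cfl > 1) {
      stop("fluid_solver: advective CFL violated (", format(cfl),
           "); reduce the time step", call. = FALSE)
    }
    adv_u <- if (stokes) 0 else advect_u(u, v, bc_old, grid)
    adv_v <- if (stokes) 0 else advect_v(u, v, bc_old, grid)
    fu <- if (is.null(forcing)) 0 else forcing$fu[2:nx, , drop = FALSE]
    fv <- if (is.null(forcing)) 0 else forcing$fv[, 2:ny, drop = FALSE]
    rhs_u <- u[2:nx, , drop = FALSE] +
      dt * (-adv_u + fu / rho) + a0 * lap_u(u, bc_old, grid) +
      (a1 / h^2) * bc_terms_u(bc_new, grid)
    rhs_v <- v[, 2:ny, drop = FALSE] +
      dt * (-adv_v + fv / rho) + a0 * lap_v(v, bc_old, grid) +
      (a1 / h^2) * bc_terms_v(bc_new, grid)
    us <- u; vs <- v
    us[2:nx, ] <- solve_u(rhs_u)
    vs[, 2:ny] <- solve_v(rhs_v)
    # impose the new boundary data on the boundary faces before projecting
    us[1, ] <- bc_new$u_left
    us[nx + 1, ] <- bc_new$u_right
    vs[, 1] <- bc_new$v_bottom
    vs[, ny + 1] <- bc_new$v_top
    pr <- project(us, vs)
    dvres <- max(abs(divergence(pr$u, pr$v, grid)))
    sc <- max(abs(pr$u), abs(pr$v)) / h
    if (dvres > div_tol * max(sc, 1e-300)) {
      stop("fluid_solver: post-projection divergence ", format(dvres),
           " exceeds tolerance", call. = FALSE)
    }
    list(u = pr$u, v = pr$v, p = pr$p, t = state$t + dt, divergence = dvres)
  }

  force_response <- function(fu, fv) {
    du <- matrix(0, nx + 1, ny)
    dv <- matrix(0, nx, ny + 1)
    du[2:nx, ] <- solve_u(dt * fu[2:nx, , drop = FALSE] / rho)
    dv[, 2:ny] <- solve_v(dt * fv[, 2:ny, drop = FALSE] / rho)
    pr <- project(du, dv)
    list(u = pr$u, v = pr$v, p = pr$p)
  }

  structure(list(step = step, force_response = force_response,
                 project = project, grid = grid, props = props, dt = dt,
                 theta = theta, stokes = stokes),
            class = "fluid_solver")
}

#' Advance the flow one time step
#'
#' Chorin projection step: explicit advection, theta-implicit diffusion,
#' external force density, then a pressure projection enforcing a discretely
#' divergence-free field. Thin wrapper around a [fluid_solver()] closure.
#'
#' @param state Flow state (`u`, `v`, `p`, `t`).
#' @param solver A [fluid_solver()].
#' @param bc_old,bc_new [wall_bc()] data at the old and new time levels.
#' @param forcing Optional list with `fu`, `fv` force-density arrays
#'   (N/m^3) on the MAC faces.
#' @return Updated state (with the divergence residual attached).
#' @export
ns_step <- function(state, solver, bc_old, bc_new, forcing = NULL) {
  solver$step(state, bc_old, bc_new, forcing)
}
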