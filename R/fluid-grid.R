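#' Uniform staggered (MAC) grid for the subtectorial space
#'
#' Cell-centered pressure, `u` on vertical faces, `v` on horizontal faces.
#' Cells are square: `h = domain_length / nx` must equal `gap_height / ny`.
#' The nominal spacing of 78 nm is realized as 78.125 nm (256 x 64 cells for
#' the 20 x 5 um domain); coarser resolutions scale `nx` and `ny` down
#' together.
#'
#' @param domain_length,gap_height Domain extents (m).
#' @param nx,ny Cell counts.
#' @return An object of class `eulerian_grid`.
#' @export
eulerian_grid <- function(domain_length = 20e-6, gap_height = 5e-6,
                          nx = 256L, ny = 64L) {
  hx <- domain_length / nx
  hy <- gap_height / ny
  if (abs(hx - hy) > 1e-9 * hx) {
    stop("eulerian_grid: cells must be square (domain_length/nx == ",
         "gap_height/ny)", call. = FALSE)
  }
  h <- hx
  structure(list(
    nx = as.integer(nx), ny = as.integer(ny), h = h,
    Lx = domain_length, Ly = gap_height,
    xu = (0:nx) * h, yu = ((1:ny) - 0.5) * h,      # u-face coordinates
    xv = ((1:nx) - 0.5) * h, yv = (0:ny) * h,      # v-face coordinates
    xp = ((1:nx) - 0.5) * h, yp = ((1:ny) - 0.5) * h
  ), class = "eulerian_grid")
}

#' @export
print.eulerian_grid <- function(x, ...) {
  cat(sprintf("<eulerian_grid>: %d x %d cells, h = %.4g nm, %.3g x %.3g um\n",
              x$nx, x$ny, x$h * 1e9, x$Lx * 1e6, x$Ly * 1e6))
  invisible(x)
}

#' Fluid properties
#'
#' @param density Fluid density (kg/m^3). Default 1000 (endolymph ~ water).
#' @param kinematic_viscosity Kinematic viscosity (m^2/s). Default
#'   0.7e-6 (0.7e-2 cm^2/s).
#' @return An object of class `fluid_props` with `rho`, `nu` and `mu`.
#' @export
fluid_props <- function(density = 1000, kinematic_viscosity = 0.7e-6) {
  stopifnot(density > 0, kinematic_viscosity > 0)
  structure(list(rho = density, nu = kinematic_viscosity,
                 mu = density * kinematic_viscosity),
            class = "fluid_props")
}

#' Empty flow state
#'
#' @param grid An [eulerian_grid()].
#' @return List with zero `u` ((nx+1) x ny), `v` (nx x (ny+1)), `p`
#'   (nx x ny) and time `t = 0`.
#' @export
flow_state <- function(grid) {
  list(u = matrix(0, grid$nx + 1L, grid$ny),
       v = matrix(0, grid$nx, grid$ny + 1L),
       p = matrix(0, grid$nx, grid$ny),
       t = 0)
}

# discrete divergence at cell centers
divergence <- function(u, v, grid) {
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  (u[2:(nx + 1), , drop = FALSE] - u[1:nx, , drop = FALSE] +
      v[, 2:(ny + 1), drop = FALSE] - v[, 1:ny, drop = FALSE]) / h
}

#' Vorticity field
#'
#' `omega = dv/dx - du/dy` by centered differences at cell corners
#' ((nx+1) x (ny+1)). One-sided values at the domain edges use the
#' boundary-condition velocities when supplied through `bc` (see
#' [wall_bc()]); otherwise edge rows/columns are computed one-sidedly from
#' the interior.
#'
#' @param u,v MAC velocity arrays.
#' @param grid An [eulerian_grid()].
#' @param bc Optional boundary-condition list.
#' @return Matrix (nx+1) x (ny+1) of vorticity (1/s) at cell corners.
#' @export
vorticity_field <- function(u, v, grid, bc = NULL) {
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  # pad v with side ghost columns and u with wall ghost rows so that the
  # centered corner stencil applies everywhere
  vs0 <- if (is.null(bc)) v[1, ] else 2 * bc$v_side - v[1, ]
  vs1 <- if (is.null(bc)) v[nx, ] else 2 * bc$v_side - v[nx, ]
  ug0 <- if (is.null(bc)) u[, 1] else 2 * bc$u_bottom - u[, 1]
  ug1 <- if (is.null(bc)) u[, ny] else 2 * bc$u_top - u[, ny]
  vpad <- rbind(vs0, v, vs1)            # (nx+2) x (ny+1)
  upad <- cbind(ug0, u, ug1)            # (nx+1) x (ny+2)
  dvdx <- (vpad[2:(nx + 2), ] - vpad[1:(nx + 1), ]) / h
  dudy <- (upad[, 2:(ny + 2)] - upad[, 1:(ny + 1)]) / h
  dvdx - dudy
}

#' Streamfunction at cell corners
#'
#' Integrates the discretely divergence-free MAC velocity:
#' `psi(i, j+1) = psi(i, j) + h u[i, j]`, `psi(i+1, j) = psi(i, j) - h v[i, j]`,
#' anchored at `psi(1, 1) = 0`. Path independence holds to the divergence
#' residual of the field.
#'
#' @inheritParams vorticity_field
#' @return Matrix (nx+1) x (ny+1).
#' @export
streamfunction <- function(u, v, grid) {
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  psi <- matrix(0, nx + 1L, ny + 1L)
  psi[1, ] <- c(0, cumsum(h * u[1, ]))
  psi[, ] <- psi[1, ][col(psi)] - rbind(0, apply(h * v[, , drop = FALSE], 2,
                                                 cumsum))[, ]
  psi
}
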