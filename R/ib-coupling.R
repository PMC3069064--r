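#' Four-point regularized delta kernel
#'
#' The piecewise-algebraic Peskin four-point kernel. It is non-negative,
#' vanishes for `|r| >= 2`, satisfies the partition of unity
#' `sum_i phi(r + i) = 1` and the first-moment condition (exact
#' interpolation of linear fields) for every real offset `r`, and
#' `phi(0) = 1/2`.
#'
#' @param r Signed distance in grid units. Vectorized.
#' @return Kernel weight(s).
#' @export
delta_weight <- function(r) {
  a <- abs(r)
  w <- numeric(length(a))
  i1 <- a < 1
  i2 <- !i1 & a < 2
  if (any(i1)) {
    w[i1] <- (3 - 2 * a[i1] + sqrt(1 + 4 * a[i1] - 4 * a[i1]^2)) / 8
  }
  if (any(i2)) {
    w[i2] <- (5 - 2 * a[i2] - sqrt(-7 + 12 * a[i2] - 4 * a[i2]^2)) / 8
  }
  w
}

# Kernel support bookkeeping for one staggered velocity component.
#
# Face positions of a MAC component are x = (i - 1 + ox) h, y = (j - 1 + oy) h
# with (ox, oy) = (0, 1/2) for u and (1/2, 0) for v. For each Lagrangian
# point this returns the 16 covered node indices and tensor-product weights;
# nodes outside the array are dropped (clipped) and counted.
kernel_stencil <- function(pts, h, ox, oy, ni, nj) {
  np <- nrow(pts)
  ix <- pts[, 1] / h + 1 - ox   # continuous 1-based index
  iy <- pts[, 2] / h + 1 - oy
  i0 <- floor(ix) - 1
  j0 <- floor(iy) - 1
  off <- 0:3
  ii <- outer(i0, off, `+`)                  # np x 4
  jj <- outer(j0, off, `+`)
  wx <- matrix(delta_weight(ix - ii), nrow = np)   # np x 4
  wy <- matrix(delta_weight(iy - jj), nrow = np)
  # expand to np x 16 (x index fast)
  I <- ii[, rep(1:4, times = 4), drop = FALSE]
  J <- jj[, rep(1:4, each = 4), drop = FALSE]
  W <- wx[, rep(1:4, times = 4), drop = FALSE] *
    wy[, rep(1:4, each = 4), drop = FALSE]
  keep <- I >= 1 & I <= ni & J >= 1 & J <= nj
  clipped <- sum(W[!keep])
  pt <- matrix(rep(seq_len(np), 16), np, 16)
  list(point = pt[keep], idx = (J[keep] - 1L) * ni + I[keep], w = W[keep],
       clipped_weight = clipped, n = np, ni = ni, nj = nj)
}

# precompute both component stencils for a set of points
ib_stencils <- function(pts, grid) {
  list(u = kernel_stencil(pts, grid$h, 0, 0.5, grid$nx + 1L, grid$ny),
       v = kernel_stencil(pts, grid$h, 0.5, 0, grid$nx, grid$ny + 1L))
}

#' Spread Lagrangian point forces onto the Eulerian grid
#'
#' `f(node) = sum_points F * phi2D((x_node - X)/h) / h^2`: point forces (N
#' per unit depth) become an Eulerian force per unit volume. Total force is
#' conserved up to the weight clipped at domain edges (the anchored bundle
#' bases sit on the reticular lamina, so a small near-wall fraction of their
#' kernel support is clipped; this is logged, not an error).
#'
#' @param F Matrix (n x 2) of point forces.
#' @param pts Matrix (n x 2) of point positions (m), or `NULL` to use
#'   precomputed stencils.
#' @param grid An [eulerian_grid()].
#' @param stencils Optional precomputed [ib_stencils] for `pts`.
#' @return List with `fu` ((nx+1) x ny) and `fv` (nx x (ny+1)) force-density
#'   arrays and the clipped weight fractions as attribute `"clipped"`.
#' @export
spread_force <- function(F, pts, grid, stencils = NULL) {
  if (is.null(stencils)) stencils <- ib_stencils(pts, grid)
  h2 <- grid$h^2
  su <- stencils$u
  sv <- stencils$v
  fu <- matrix(0, grid$nx + 1L, grid$ny)
  fv <- matrix(0, grid$nx, grid$ny + 1L)
  acc_u <- rowsum(su$w * F[su$point, 1] / h2, su$idx)
  fu[as.integer(rownames(acc_u))] <- acc_u
  acc_v <- rowsum(sv$w * F[sv$point, 2] / h2, sv$idx)
  fv[as.integer(rownames(acc_v))] <- acc_v
  structure(list(fu = fu, fv = fv),
            clipped = c(u = su$clipped_weight, v = sv$clipped_weight))
}

#' Interpolate grid velocities to Lagrangian points
#'
#' Adjoint of [spread_force()] (without the cell-area factor):
#' `U(point) = sum_nodes u * phi2D`. Exact for constant and linear fields.
#'
#' @param u,v Velocity component arrays on the MAC grid.
#' @inheritParams spread_force
#' @return Matrix (n x 2) of point velocities.
#' @export
interpolate_velocity <- function(u, v, pts, grid, stencils = NULL) {
  if (is.null(stencils)) stencils <- ib_stencils(pts, grid)
  su <- stencils$u
  sv <- stencils$v
  U <- matrix(0, su$n, 2)
  au <- rowsum(su$w * u[su$idx], su$point)
  U[as.integer(rownames(au)), 1] <- au
  av <- rowsum(sv$w * v[sv$idx], sv$point)
  U[as.integer(rownames(av)), 2] <- av
  U
}

#' Advance Lagrangian points with the local fluid velocity
#'
#' Explicit no-slip update `X' = X + dt U`. Anchored points are overridden
#' by their prescribed positions when supplied.
#'
#' @param X Matrix (n x 2) of positions.
#' @param U Matrix (n x 2) of velocities.
#' @param dt Time step (s), positive.
#' @param anchored Logical vector (n), or `NULL`.
#' @param prescribed Matrix of prescribed positions for anchored points
#'   (n x 2, only anchored rows are read), or `NULL`.
#' @return Updated position matrix.
#' @export
advance_boundary <- function(X, U, dt, anchored = NULL, prescribed = NULL) {
  stopifnot(dt > 0)
  Xp <- X + dt * U
  if (!is.null(anchored) && any(anchored) && !is.null(prescribed)) {
    Xp[anchored, ] <- prescribed[anchored, , drop = FALSE]
  }
  Xp
}
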