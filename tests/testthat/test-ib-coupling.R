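test_that("four-point kernel has the closed-form values and compact support", {
  expect_equal(delta_weight(0), 0.5)
  expect_equal(delta_weight(c(-2.5, 2, 2.5, -3)), rep(0, 4))
  r <- seq(-2.2, 2.2, by = 0.01)
  expect_true(all(delta_weight(r) >= 0))
  expect_true(all(delta_weight(r[abs(r) >= 2]) == 0))
})

test_that("kernel satisfies partition of unity and the first moment", {
  set.seed(1)
  for (r in c(0, 0.25, runif(10))) {
    nodes <- -2:3
    w <- delta_weight(r - nodes)
    expect_equal(sum(w), 1, tolerance = 1e-14)
    # first moment: exact reproduction of the coordinate itself
    expect_equal(sum(nodes * w), r, tolerance = 1e-13)
  }
})

test_that("spreading conserves force and puts phi(0)^2 on a coincident node", {
  g <- eulerian_grid(nx = 64L, ny = 16L)
  set.seed(2)
  pts <- cbind(runif(12, 2e-6, 18e-6), runif(12, 1e-6, 4e-6))
  F <- matrix(rnorm(24), 12, 2)
  f <- spread_force(F, pts, g)
  expect_equal(sum(f$fu) * g$h^2, sum(F[, 1]), tolerance = 1e-12)
  expect_equal(sum(f$fv) * g$h^2, sum(F[, 2]), tolerance = 1e-12)
  expect_equal(unname(attr(f, "clipped")), c(0, 0))
  # a point exactly on a u-face receives phi(0)^2 = 1/4 there
  pt <- matrix(c(10e-6, 2.5e-6 - g$h / 2), 1)
  fs <- spread_force(matrix(c(1, 0), 1), pt, g)
  expect_equal(max(fs$fu) * g$h^2, 0.25, tolerance = 1e-14)
  # zero forces spread to an identically zero field
  fz <- spread_force(matrix(0, 12, 2), pts, g)
  expect_true(all(fz$fu == 0) && all(fz$fv == 0))
})

test_that("interpolation is exact for constant and linear fields", {
  g <- eulerian_grid(nx = 64L, ny = 16L)
  set.seed(3)
  pts <- cbind(runif(15, 2e-6, 18e-6), runif(15, 1e-6, 4e-6))
  u0 <- matrix(1.7e-5, g$nx + 1, g$ny)
  v0 <- matrix(-0.4e-5, g$nx, g$ny + 1)
  U <- interpolate_velocity(u0, v0, pts, g)
  expect_equal(U[, 1], rep(1.7e-5, 15), tolerance = 1e-14)
  expect_equal(U[, 2], rep(-0.4e-5, 15), tolerance = 1e-14)
  # linear shear field reproduced at the points to rounding
  gam <- 3e2
  ul <- matrix(rep(gam * g$yu, each = g$nx + 1), g$nx + 1)
  Ul <- interpolate_velocity(ul, v0 * 0, pts, g)
  expect_equal(Ul[, 1], gam * pts[, 2], tolerance = 1e-10)
})

test_that("spreading and interpolation are adjoint", {
  g <- eulerian_grid(nx = 64L, ny = 16L)
  set.seed(4)
  pts <- cbind(runif(20, 2e-6, 18e-6), runif(20, 1e-6, 4e-6))
  F <- matrix(rnorm(40), 20, 2)
  u <- matrix(rnorm((g$nx + 1) * g$ny), g$nx + 1)
  v <- matrix(rnorm(g$nx * (g$ny + 1)), g$nx)
  f <- spread_force(F, pts, g)
  U <- interpolate_velocity(u, v, pts, g)
  lhs <- (sum(f$fu * u) + sum(f$fv * v)) * g$h^2
  expect_equal(lhs, sum(F * U), tolerance = 1e-12 * max(abs(lhs), 1))
})

test_that("spreading conserves torque about any fixed point (interior)", {
  g <- eulerian_grid(nx = 64L, ny = 16L)
  set.seed(8)
  pts <- cbind(runif(10, 4e-6, 16e-6), runif(10, 1.5e-6, 3.5e-6))
  F <- matrix(rnorm(20), 10, 2)
  f <- spread_force(F, pts, g)
  xu <- outer(g$xu, rep(1, g$ny)); yu <- outer(rep(1, g$nx + 1), g$yu)
  xv <- outer(g$xv, rep(1, g$ny + 1)); yv <- outer(rep(1, g$nx), g$yv)
  tq_grid <- (sum(xv * f$fv) - sum(yu * f$fu)) * g$h^2
  tq_pts <- sum(pts[, 1] * F[, 2] - pts[, 2] * F[, 1])
  expect_equal(tq_grid, tq_pts, tolerance = 1e-4 * max(abs(tq_pts), 1e-12))
})

test_that("interpolation-after-spreading error of a smooth field is O(h^2)", {
  smooth_err <- function(fac) {
    g <- eulerian_grid(nx = 64L * fac, ny = 16L * fac)
    pts <- cbind(seq(4e-6, 16e-6, length.out = 9),
                 seq(1.2e-6, 3.8e-6, length.out = 9))
    uf <- function(x, y) sin(2 * pi * x / g$Lx) * cos(pi * y / g$Ly)
    u <- outer(g$xu, g$yu, uf)
    v <- matrix(0, g$nx, g$ny + 1)
    U <- interpolate_velocity(u, v, pts, g)
    max(abs(U[, 1] - uf(pts[, 1], pts[, 2])))
  }
  e1 <- smooth_err(1L)
  e2 <- smooth_err(2L)
  expect_gt(e1 / e2, 3)  # ~ 2nd order under grid refinement
})

test_that("boundary advance is the explicit no-slip update", {
  X <- matrix(c(1e-6, 2e-6), 1)
  U <- matrix(c(1e-3, 0), 1)
  expect_equal(advance_boundary(X, U, 5e-6), X + c(5e-9, 0))
  expect_equal(advance_boundary(X, U * 0, 5e-6), X)
  # rigid uniform velocity preserves all pairwise distances
  set.seed(6)
  Xs <- matrix(runif(12, 0, 1e-5), 6, 2)
  Us <- matrix(rep(c(2e-3, -1e-3), each = 6), 6, 2)
  Xp <- advance_boundary(Xs, Us, 1e-5)
  expect_equal(as.numeric(dist(Xp)), as.numeric(dist(Xs)),
               tolerance = 1e-12)
  # anchored points are overridden by prescribed positions
  presc <- Xs + 1e-9
  anch <- c(TRUE, rep(FALSE, 5))
  Xa <- advance_boundary(Xs, Us, 1e-5, anchored = anch, prescribed = presc)
  expect_equal(Xa[1, ], presc[1, ])
  expect_error(advance_boundary(Xs, Us, -1), "dt > 0")
})

test_that("near-edge points are clipped with the weight accounted", {
  g <- eulerian_grid(nx = 64L, ny = 16L)
  pt <- matrix(c(10e-6, 0.1 * g$h), 1)  # just above the bottom wall
  f <- spread_force(matrix(c(0, 1), 1), pt, g)
  cl <- attr(f, "clipped")
  expect_gt(cl[["v"]], 0)
  expect_equal(sum(f$fv) * g$h^2 + cl[["v"]], 1, tolerance = 1e-12)
})
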