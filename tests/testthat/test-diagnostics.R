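test_that("transport estimates reproduce the closed-form rates", {
  est <- transport_estimates()
  # D/l^2 with D = 4e-6 cm^2/s and l = 170 nm
  expect_equal(est$diffusion_rate, 4e-10 / (170e-9)^2, tolerance = 1e-12)
  expect_equal(est$diffusion_rate, 1.384e4, tolerance = 1e-3)
  # diffusion time is the exact reciprocal: ~72 us
  expect_equal(est$diffusion_rate * est$diffusion_time, 1, tolerance = 1e-12)
  expect_equal(est$diffusion_time, 72.25e-6, tolerance = 1e-3)
  # concentration-proportional carrier split of 500 pA: ~2e5 ions/s
  expect_equal(est$ca_influx_rate,
               500e-12 * (20e-6 / (20e-6 + 160e-3)) / (2 * 1.602176634e-19),
               tolerance = 1e-12)
  expect_gt(est$ca_influx_rate, 1e5)
  expect_lt(est$ca_influx_rate, 1e6)
  # critical elongation time ~0.39 us, verified against a numerical root
  f <- function(tau) rayleigh_vorticity(5e-9, 0.7e-6, tau) -
    est$diffusion_rate
  root <- uniroot(f, c(1e-8, 1e-5), tol = 1e-18)$root
  expect_equal(est$tau_crit, root, tolerance = 1e-6)
  expect_lt(est$tau_crit, 1e-6)
})

test_that("Rayleigh vorticity has the stated closed form and monotonicity", {
  expect_equal(rayleigh_vorticity(5e-9, 0.7e-6, 1e-6),
               (5e-9 / 1e-6) / sqrt(pi * 0.7e-6 * 1e-6), tolerance = 1e-12)
  expect_equal(rayleigh_vorticity(5e-9, 0.7e-6, 1e-6), 3.4e3,
               tolerance = 0.02)
  # linear in A
  expect_equal(rayleigh_vorticity(10e-9, 0.7e-6, 1e-6),
               2 * rayleigh_vorticity(5e-9, 0.7e-6, 1e-6))
  # strictly decreasing in tau_o
  taus <- 10^seq(-7, -5, length.out = 9)
  om <- rayleigh_vorticity(5e-9, 0.7e-6, taus)
  expect_true(all(diff(om) < 0))
  expect_error(rayleigh_vorticity(-1e-9, 0.7e-6, 1e-6))
})

test_that("free-end reflection doubles the incident displacement
           (d'Alembert oracle)", {
  res <- free_end_reflection(n_cells = 600L)
  # image-source solution: u(L, t) = 2 g(L - c t) for the incident pulse,
  # so the free-end peak is exactly twice the incident peak
  expect_equal(res$ratio, 2, tolerance = 1e-6)
  # oracle trace: evaluate the d'Alembert images solution at the free end
  L <- 4.5e-6; c0 <- sqrt(2.3e9 / 1000); sig <- 0.02 * L
  oracle <- 2e-9 * exp(-0.5 * ((L / 2 + c0 * res$t - L) / sig)^2)
  expect_lt(max(abs(res$end_trace - oracle)), 1e-3 * max(oracle))
})

test_that("vortex detector finds a constructed eddy and ignores shear", {
  g <- eulerian_grid(nx = 64L, ny = 16L)
  xc <- 10e-6; yc <- 2.5e-6; a <- 0.4e-6
  # Gaussian vortex patch (solid-body-like core) superimposed on uniform flow
  vort_u <- function(x, y) {
    r2 <- (x - xc)^2 + (y - yc)^2
    -50 * (y - yc) * exp(-r2 / a^2)
  }
  vort_v <- function(x, y) {
    r2 <- (x - xc)^2 + (y - yc)^2
    50 * (x - xc) * exp(-r2 / a^2)
  }
  U0 <- 2e-5
  u <- outer(g$xu, g$yu, vort_u) + U0
  v <- outer(g$xv, g$yv, vort_v)
  w <- vorticity_field(u, v, g)
  rep1 <- detect_vortices(w, u, v, g)
  expect_equal(nrow(rep1), 1L)
  expect_lt(abs(rep1$x - xc), 2 * g$h)
  expect_lt(abs(rep1$y - yc), 2 * g$h)
  expect_equal(rep1$circulation_sign, 1)
  # Galilean invariance: a different uniform flow leaves the detection alone
  rep2 <- detect_vortices(w, u + 3e-4, v - 1e-4, g)
  expect_equal(rep2$x, rep1$x)
  expect_equal(rep2$y, rep1$y)
  # pure linear shear: constant vorticity, open streamlines, no detection
  gam <- 10
  us <- gam * outer(rep(1, g$nx + 1), g$yu)
  vs <- matrix(0, g$nx, g$ny + 1)
  ws <- vorticity_field(us, vs, g)
  expect_equal(nrow(detect_vortices(ws, us, vs, g)), 0L)
})

test_that("peak phase interpolation refines the discrete argmax", {
  ph <- seq(0, 719, by = 5)
  val <- cos((ph - 123.4) * pi / 180)
  expect_equal(peak_phase(ph, val), 123.4, tolerance = 0.2)
})

test_that("row kinematics are zero under rigid translation and
           frame-consistent", {
  rec <- cached_zero_drive()
  # forge a rigid translation of the recorded positions: rotation and
  # length change must remain exactly zero
  rec2 <- rec
  rec2$positions <- rec$positions + 1e-8
  rec2$scenario$n_transient_cycles <- 0L
  rk <- row_kinematics(rec2, analyzed_only = FALSE)
  for (k in rk) {
    expect_equal(max(abs(k$rotation_rad)), 0)
    expect_lt(max(abs(k$length_change_nm)), 1e-6)
  }
  # frame consistency: subtracting the recorded RL displacement (lab ->
  # RL frame) leaves chord rotation and arclength unchanged
  rec3 <- rec2
  for (s in seq_len(dim(rec3$positions)[3])) {
    rec3$positions[, 1, s] <- rec3$positions[, 1, s] -
      rec3$rl_displacement[s, 1]
    rec3$positions[, 2, s] <- rec3$positions[, 2, s] -
      rec3$rl_displacement[s, 2]
  }
  rk3 <- row_kinematics(rec3, analyzed_only = FALSE)
  for (nm in names(rk)) {
    expect_equal(rk3[[nm]]$rotation_rad, rk[[nm]]$rotation_rad,
                 tolerance = 1e-12)
    expect_equal(rk3[[nm]]$length_change_nm, rk[[nm]]$length_change_nm,
                 tolerance = 1e-9)
  }
})

test_that("a zero-amplitude drive produces identically zero stretch", {
  rec <- cached_zero_drive()
  expect_equal(max(abs(rec$stretch)), 0)
  expect_equal(max(abs(rec$tension)), 0)
  tr <- tip_link_trace(structure(rec, class = "run_record"))
  expect_true(all(vapply(tr, function(t) all(t$stretch_nm == 0), logical(1))))
})
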