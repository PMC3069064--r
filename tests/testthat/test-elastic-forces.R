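test_that("stretching force matches the closed-form segment tension", {
  p <- elastic_params()
  # rest geometry: zero force everywhere
  chain <- straight_chain(5)
  expect_equal(max(abs(stretching_force(chain, p))), 0)
  # one segment, d = 200 nm, strain 1e-3, E = 2.3 GPa:
  # tension = E * (pi d^2/4) * strain = 7.2257e-8 N
  seg <- straight_chain(2)
  seg$X[2, 2] <- 75e-9 * 1.001
  F <- stretching_force(seg, p)
  expect_equal(sqrt(sum(F[1, ]^2)),
               2.3e9 * pi * (200e-9)^2 / 4 * 1e-3, tolerance = 1e-10)
  expect_equal(F[1, ], -F[2, ])        # equal and opposite
  expect_gt(F[1, 2], 0)                # stretched segment pulls ends together
  # interior point of a uniformly stretched chain carries zero net force
  ch <- straight_chain(6)
  ch$X[, 2] <- ch$X[, 2] * 1.002
  Fu <- stretching_force(ch, p)
  expect_lt(max(abs(Fu[2:5, ])), 1e-18)
  # coincident points are a degenerate segment
  bad <- straight_chain(3)
  bad$X[2, ] <- bad$X[1, ]
  expect_error(stretching_force(bad, p), "degenerate")
})

test_that("bending force vanishes on straight triads and balances internally", {
  p <- elastic_params()
  chain <- straight_chain(6)
  expect_equal(max(abs(bending_force(chain, p))), 0)
  # perturbed chain: the three forces of each isolated triad sum to zero
  set.seed(7)
  tri <- straight_chain(3)
  tri$X <- tri$X + matrix(rnorm(6, sd = 2e-9), 3, 2)
  Fb <- bending_force(tri, p)
  expect_lt(max(abs(colSums(Fb))), 1e-12 * max(abs(Fb)))
})

test_that("elastic forces equal minus the energy gradient (FD oracle)", {
  p <- elastic_params()
  b <- build_bundle(bundle_config())
  set.seed(42)
  rows <- b$rows
  for (k in 1:3) {
    rows[[k]]$X <- rows[[k]]$X + matrix(rnorm(length(rows[[k]]$X), sd = 1e-10),
                                        ncol = 2)
  }
  F <- total_force_density(rows, b$links, p)
  dd <- 1e-13
  for (trial in 1:25) {
    k <- sample(3, 1)
    i <- sample(nrow(rows[[k]]$X), 1)
    cc <- sample(2, 1)
    rp <- rows; rp[[k]]$X[i, cc] <- rp[[k]]$X[i, cc] + dd
    rm <- rows; rm[[k]]$X[i, cc] <- rm[[k]]$X[i, cc] - dd
    fd <- -(elastic_energy(rp, b$links, p) -
              elastic_energy(rm, b$links, p)) / (2 * dd)
    expect_equal(F[[k]][i, cc], fd, tolerance = 1e-6)
  }
})

test_that("elastic energy is non-negative and zero exactly at rest", {
  p <- elastic_params()
  b <- build_bundle(bundle_config())
  expect_lt(elastic_energy(b$rows, b$links, p), 1e-30)
  set.seed(11)
  rows <- b$rows
  rows[[1]]$X <- rows[[1]]$X + matrix(rnorm(length(rows[[1]]$X), sd = 1e-10),
                                      ncol = 2)
  expect_gt(elastic_energy(rows, b$links, p), 0)
})

test_that("internal forces of an untethered structure conserve momentum", {
  p <- elastic_params()
  b <- build_bundle(bundle_config())
  set.seed(3)
  rows <- b$rows
  for (k in 1:3) {
    rows[[k]]$X <- rows[[k]]$X + matrix(rnorm(length(rows[[k]]$X), sd = 5e-10),
                                        ncol = 2)
  }
  F <- total_force_density(rows, b$links, p)
  tot <- Reduce(`+`, lapply(F, colSums))
  expect_lt(max(abs(tot)), 1e-10 * max(abs(unlist(F))))
})

test_that("link force is a signed linear spring", {
  p <- elastic_params()
  b <- build_bundle(bundle_config())
  lk <- b$links$upper_tip_link
  # displace the middle-row tip 10 nm along the link direction
  ab <- ciliasim:::resolve_link(lk, b$rows)
  e <- (ab$b - ab$a) / sqrt(sum((ab$b - ab$a)^2))
  rows <- b$rows
  rows$middle$X[ab$i1, ] <- rows$middle$X[ab$i1, ] - 10e-9 * e
  lf <- link_force(lk, rows)
  expect_equal(lf$tension, 5e-4 * 10e-9, tolerance = 1e-9)  # 5 pN
  # compression: signed tension -5 pN
  rows2 <- b$rows
  rows2$middle$X[ab$i1, ] <- rows2$middle$X[ab$i1, ] + 10e-9 * e
  expect_equal(link_force(lk, rows2)$tension, -5e-4 * 10e-9,
               tolerance = 1e-9)
  expect_equal(link_force(lk, b$rows)$tension, 0, tolerance = 1e-25)
})

test_that("gate opens at threshold, ramps by 5 nm, and latches", {
  b <- build_bundle(bundle_config())
  lk <- b$links$lower_tip_link
  Tg <- lk$gate$threshold
  lk1 <- gate_update(lk, 0.99 * Tg, time = 1e-4)
  expect_false(lk1$gate$is_open)
  lk2 <- gate_update(lk1, Tg, time = 2e-4)
  expect_true(lk2$gate$is_open)
  # after the elongation time the rest length has grown by exactly 5 nm
  lk2$gate$now <- 2e-4 + 2 * lk2$gate$tau_o
  expect_equal(ciliasim:::current_rest_length(lk2),
               lk2$rest_length + 5e-9)
  # mid-ramp the increment is partial
  lk2$gate$now <- 2e-4 + 0.5 * lk2$gate$tau_o
  expect_equal(ciliasim:::current_rest_length(lk2),
               lk2$rest_length + 2.5e-9)
  # latch: tension collapse does not reclose by default
  lk3 <- gate_update(lk2, 0, time = 3e-4)
  expect_true(lk3$gate$is_open)
  # compression never opens a closed gate
  lk4 <- gate_update(lk, -10 * Tg, time = 1e-4)
  expect_false(lk4$gate$is_open)
})

test_that("gate state is monotone in the running max of tension (latch rule)", {
  b <- build_bundle(bundle_config())
  lk <- b$links$upper_tip_link
  Tg <- lk$gate$threshold
  set.seed(5)
  tensions <- Tg * runif(50, 0, 1.4)
  open_seen <- FALSE
  for (i in seq_along(tensions)) {
    lk <- gate_update(lk, tensions[i], time = i * 1e-5)
    if (open_seen) expect_true(lk$gate$is_open)
    open_seen <- open_seen || lk$gate$is_open
    expect_equal(lk$gate$is_open, max(tensions[1:i]) >= Tg)
  }
})

test_that("optional hysteresis recloses below the configured fraction", {
  g <- gate_state(reclose = TRUE, reclose_fraction = 0.5)
  b <- build_bundle(bundle_config())
  lk <- attach_links(b$rows, bundle_config(), gate = g)$upper_tip_link
  Tg <- lk$gate$threshold
  lk <- gate_update(lk, Tg, time = 1e-4)
  expect_true(lk$gate$is_open)
  lk <- gate_update(lk, 0.6 * Tg, time = 2e-4)
  expect_true(lk$gate$is_open)
  lk <- gate_update(lk, 0.4 * Tg, time = 3e-4)
  expect_false(lk$gate$is_open)
})

test_that("total force density is zero at rest and propagates link forces", {
  p <- elastic_params()
  b <- build_bundle(bundle_config())
  F <- total_force_density(b$rows, b$links, p)
  expect_lt(max(abs(unlist(F[1:3]))), 1e-15)
  expect_equal(length(attr(F, "link_tensions")), 8L)
  expect_lt(max(abs(attr(F, "link_tensions"))), 1e-18)
})
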