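test_that("default geometry realizes the printed dimensions", {
  cfg <- bundle_config()
  expect_equal(cfg$tallest_height, 4.5e-6)   # 5 um gap minus 0.5 um clearance
  b <- build_bundle(cfg)
  # 4.5 um at 75 nm spacing: 60 segments, 61 points on the tallest row
  expect_equal(nrow(b$rows$tallest$X), 61L)
  expect_equal(length(b$rows$tallest$rest_segment_lengths), 60L)
  expect_true(all(abs(b$rows$tallest$rest_segment_lengths - 75e-9) < 1e-20))
  # rows strictly ordered and centered around the middle of the domain
  hts <- vapply(b$rows, function(r) max(r$X[, 2]), numeric(1))
  expect_true(all(diff(hts) < 0))
  expect_equal(unname(b$rows$middle$X[1, 1]), cfg$domain_length / 2)
  # all points inside the fluid domain (bases on the bottom boundary)
  for (r in b$rows) {
    expect_true(all(r$X[, 1] > 0 & r$X[, 1] < cfg$domain_length))
    expect_true(all(r$X[, 2] >= 0 & r$X[, 2] < cfg$gap_height))
  }
  # only the basal insertion point is anchored
  expect_equal(vapply(b$rows, function(r) sum(r$anchored), integer(1)),
               c(tallest = 1L, middle = 1L, shortest = 1L))
})

test_that("widened-gap configuration keeps the rows and grows the clearance", {
  cfg <- bundle_config(gap_height = 10e-6, tm_clearance = 5.5e-6)
  expect_equal(cfg$tallest_height, 4.5e-6)
  b <- build_bundle(cfg)
  expect_equal(max(b$rows$tallest$X[, 2]), 4.5e-6)
})

test_that("taper profile is piecewise linear over the basal third", {
  cfg <- bundle_config()
  expect_equal(taper_profile(0, cfg), cfg$base_diameter)
  expect_equal(taper_profile(1, cfg), cfg$shaft_diameter)
  expect_equal(taper_profile(0.5, cfg), cfg$shaft_diameter)
  expect_equal(taper_profile(1 / 3, cfg), cfg$shaft_diameter)
  expect_equal(taper_profile(1 / 6, cfg),
               (cfg$base_diameter + cfg$shaft_diameter) / 2)
  expect_error(taper_profile(-0.1, cfg), "\\[0, 1\\]")
  expect_error(taper_profile(1.1, cfg), "\\[0, 1\\]")
})

test_that("links: two gated tip links and six ungated horizontal connectors", {
  b <- build_bundle(bundle_config())
  gated <- vapply(b$links, function(l) !is.null(l$gate), logical(1))
  expect_equal(sum(gated), 2L)
  expect_equal(sum(!gated), 6L)
  kinds <- vapply(b$links, function(l) l$kind, character(1))
  expect_setequal(unique(kinds[gated]), c("upper_tip_link", "lower_tip_link"))
  # upper tip link joins middle tip to the tallest shaft, lower joins
  # shortest tip to the middle shaft
  up <- b$links$upper_tip_link
  expect_setequal(vapply(up$endpoints, `[`, character(1), 1),
                  c("middle", "tallest"))
  lo <- b$links$lower_tip_link
  expect_setequal(vapply(lo$endpoints, `[`, character(1), 1),
                  c("shortest", "middle"))
  # tip-link rest length is exactly 170 nm with the default spacing
  expect_equal(up$rest_length, 170e-9, tolerance = 1e-12)
  expect_equal(lo$rest_length, 170e-9, tolerance = 1e-12)
  # every link starts at zero extension
  p <- elastic_params()
  for (l in b$links) {
    lf <- link_force(l, b$rows)
    expect_lt(abs(lf$extension), 1e-15)
  }
  # connectors are horizontal at rest
  for (l in b$links[!gated]) {
    ab <- ciliasim:::resolve_link(l, b$rows)
    expect_lt(abs(ab$a[2] - ab$b[2]), 1e-15)
  }
})

test_that("geometry is rebuilt deterministically and exports a point table", {
  b1 <- build_bundle(bundle_config())
  b2 <- build_bundle(bundle_config())
  expect_identical(b1$rows$tallest$X, b2$rows$tallest$X)
  expect_identical(b1$rows$shortest$local_diameters,
                   b2$rows$shortest$local_diameters)
  tab <- geometry_table(b1)
  expect_equal(nrow(tab), sum(vapply(b1$rows, function(r) nrow(r$X),
                                     integer(1))))
  expect_named(tab, c("boundary_id", "point", "x", "y", "diameter",
                      "anchored"))
})

test_that("invalid configurations fail with informative errors", {
  expect_error(bundle_config(gap_height = 0.4e-6, tm_clearance = 0.5e-6),
               "tallest row height")
  expect_error(bundle_config(row_height_ratios = c(1, 0.7, 0.8)),
               "strictly decreasing")
  expect_error(bundle_config(shaft_diameter = -1e-9), "positive")
  expect_error(bundle_config(n_top_connectors = 4L), "six")
  cfg <- bundle_config(inter_row_spacing = 200e-9)
  b <- build_bundle(bundle_config())
  expect_error(attach_links(b$rows, cfg), "rest length")
})
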