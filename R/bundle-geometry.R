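#' Stereocilium taper profile
#'
#' Local diameter of a stereocilium as a function of relative height. The
#' basal `base_fraction` (default one third) of the total height carries a
#' linear taper from `base_diameter` to `shaft_diameter`; above it the
#' diameter is constant.
#'
#' @param s Height fraction along the stereocilium, in `[0, 1]` (0 = insertion
#'   into the reticular lamina, 1 = tip). Vectorized.
#' @param config A [bundle_config()].
#' @return Diameter (m), same length as `s`.
#' @export
#' @examples
#' cfg <- bundle_config()
#' taper_profile(0, cfg)     # base diameter
#' taper_profile(0.5, cfg)   # shaft diameter
taper_profile <- function(s, config) {
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1)) {
    stop("taper_profile: height fraction s must lie in [0, 1]", call. = FALSE)
  }
  f <- config$base_fraction
  w <- pmin(s / f, 1)
  config$base_diameter + (config$shaft_diameter - config$base_diameter) * w
}

#' Build the Lagrangian boundaries of the three stereocilia rows
#'
#' Constructs one ordered elastic point chain per row, centered in the fluid
#' domain. The tallest row sits on the left (its tip links point up-left from
#' the shorter rows): with the drive convention used here, phase 180 degrees
#' (reticular lamina maximally right and down) then corresponds to positive
#' tip-link stretch. Points are spaced `lagrangian_spacing` apart at rest;
#' only the basal insertion point of each row is anchored (kinematically
#' prescribed to follow the reticular lamina), so a row is free to pivot
#' about its insertion.
#'
#' @param config A [bundle_config()].
#' @return A list with elements `rows` (list of three `lagrangian_boundary`
#'   objects, tallest to shortest) and `links` (from [attach_links()]).
#' @export
build_bundle <- function(config) {
  validate_bundle_config(config)
  r0 <- config$lagrangian_spacing
  heights <- config$tallest_height * config$row_height_ratios
  nseg <- round(heights / r0)
  heights <- nseg * r0  # snap to an integer number of segments
  ids <- c("tallest", "middle", "shortest")
  # tallest on the left: offsets -s, 0, +s about the bundle center
  xs <- config$bundle_center_x +
    c(-config$inter_row_spacing, 0, config$inter_row_spacing)

  rows <- vector("list", 3L)
  for (k in 1:3) {
    n_pts <- nseg[k] + 1L
    y <- seq(0, heights[k], by = r0)
    X <- cbind(rep(xs[k], n_pts), y)
    diam <- taper_profile(y / heights[k], config)
    rows[[k]] <- new_lagrangian_boundary(
      boundary_id = ids[k],
      X = X,
      rest_segment_lengths = rep(r0, nseg[k]),
      local_diameters = diam,
      anchored = c(TRUE, rep(FALSE, n_pts - 1L))
    )
  }
  names(rows) <- ids
  # all points strictly inside the fluid rectangle except the anchored bases,
  # which sit on the reticular lamina itself
  top <- max(vapply(rows, function(r) max(r$X[, 2]), numeric(1)))
  if (top >= config$gap_height) {
    stop("build_bundle: rows reach the tectorial membrane; reduce heights or ",
         "widen the gap", call. = FALSE)
  }
  links <- attach_links(rows, config)
  list(rows = rows, links = links)
}

new_lagrangian_boundary <- function(boundary_id, X, rest_segment_lengths,
                                    local_diameters, anchored,
                                    theta0 = NULL) {
  n <- nrow(X)
  stopifnot(length(rest_segment_lengths) == n - 1L,
            length(local_diameters) == n, length(anchored) == n)
  if (is.null(theta0)) {
    theta0 <- if (n >= 3) triad_angles(X) else numeric(0)
  }
  structure(
    list(boundary_id = boundary_id, X = X,
         rest_segment_lengths = rest_segment_lengths,
         local_diameters = local_diameters,
         anchored = anchored, theta0 = theta0),
    class = "lagrangian_boundary"
  )
}

#' @export
print.lagrangian_boundary <- function(x, ...) {
  cat(sprintf("<lagrangian_boundary '%s'>: %d points, height %.3f um, %d anchored\n",
              x$boundary_id, nrow(x$X), diff(range(x$X[, 2])) * 1e6,
              sum(x$anchored)))
  invisible(x)
}

# signed exterior angle at each interior point of a chain
triad_angles <- function(X) {
  n <- nrow(X)
  t1 <- X[2:(n - 1), , drop = FALSE] - X[1:(n - 2), , drop = FALSE]
  t2 <- X[3:n, , drop = FALSE] - X[2:(n - 1), , drop = FALSE]
  atan2(t1[, 1] * t2[, 2] - t1[, 2] * t2[, 1],
        t1[, 1] * t2[, 1] + t1[, 2] * t2[, 2])
}

#' Attach tip links and horizontal top connectors to the rows
#'
#' Creates the two gated tip links (upper: tallest-middle, lower:
#' middle-shortest) and six ungated horizontal top connectors (three per
#' adjacent-row pair, evenly spaced over the top 10 percent of the shorter
#' member). The tip-link attachment on the taller row is the Lagrangian point
#' nearest to the height that realizes the configured rest length; with the
#' default inter-row spacing this is exactly one point spacing above the
#' shorter row's tip and the rest length is exactly 170 nm.
#'
#' @param rows List of the three row boundaries from [build_bundle()].
#' @param config A [bundle_config()].
#' @param k_link Link stiffness (N/m). Default `5e-4`.
#' @param gate Gate parameters for the tip links, from [gate_state()].
#' @return List of `link_element` objects (2 gated tip links then 6 ungated
#'   connectors).
#' @export
attach_links <- function(rows, config, k_link = 5e-4, gate = gate_state()) {
  l <- config$tip_link_rest_length
  s <- config$inter_row_spacing
  if (s >= l) {
    stop("attach_links: inter_row_spacing exceeds the tip-link rest length; ",
         "no attachment can realize it", call. = FALSE)
  }
  r0 <- config$lagrangian_spacing
  dy <- sqrt(l^2 - s^2)
  links <- list()

  tip_link <- function(kind, short_id, tall_id) {
    ns <- nrow(rows[[short_id]]$X)
    i_att <- ns - 1L + as.integer(round(dy / r0)) + 1L  # 1-based on taller row
    if (i_att < 1L || i_att > nrow(rows[[tall_id]]$X)) {
      stop("attach_links: tip-link attachment height falls outside the '",
           tall_id, "' row", call. = FALSE)
    }
    a <- rows[[short_id]]$X[ns, ]
    b <- rows[[tall_id]]$X[i_att, ]
    rest <- sqrt(sum((b - a)^2))
    if (abs(rest - l) > r0 / 2) {
      stop("attach_links: cannot realize the tip-link rest length within half ",
           "a point spacing for the configured inter_row_spacing",
           call. = FALSE)
    }
    new_link_element(kind = kind,
                     endpoints = list(c(short_id, ns), c(tall_id, i_att)),
                     rest_length = rest, stiffness = k_link, gate = gate)
  }
  links[["upper_tip_link"]] <- tip_link("upper_tip_link", "middle", "tallest")
  links[["lower_tip_link"]] <- tip_link("lower_tip_link", "shortest", "middle")

  connector_pair <- function(short_id, tall_id, tag) {
    ns <- nrow(rows[[short_id]]$X)
    n_short_seg <- ns - 1L
    idx0 <- unique(round(seq(0.9 * n_short_seg, n_short_seg, length.out = 3)))
    out <- list()
    for (j in seq_along(idx0)) {
      i_s <- as.integer(idx0[j]) + 1L
      i_t <- i_s  # same height on the taller row (same spacing from the base)
      a <- rows[[short_id]]$X[i_s, ]
      b <- rows[[tall_id]]$X[i_t, ]
      out[[sprintf("top_connector_%s_%d", tag, j)]] <-
        new_link_element(kind = "top_connector",
                         endpoints = list(c(short_id, i_s), c(tall_id, i_t)),
                         rest_length = sqrt(sum((b - a)^2)),
                         stiffness = k_link, gate = NULL)
    }
    out
  }
  links <- c(links,
             connector_pair("middle", "tallest", "tm"),
             connector_pair("shortest", "middle", "ms"))
  if (sum(vapply(links, function(x) x$kind == "top_connector", logical(1))) !=
      config$n_top_connectors) {
    stop("attach_links: could not place ", config$n_top_connectors,
         " distinct top connectors with this geometry", call. = FALSE)
  }
  links
}

new_link_element <- function(kind, endpoints, rest_length, stiffness, gate) {
  structure(list(kind = kind, endpoints = endpoints,
                 rest_length = rest_length, stiffness = stiffness,
                 gate = gate),
            class = "link_element")
}

#' @export
print.link_element <- function(x, ...) {
  ep <- vapply(x$endpoints, function(e) paste0(e[1], "[", e[2], "]"),
               character(1))
  cat(sprintf("<link_element %s>: %s -- %s, rest %.1f nm, k = %g N/m%s\n",
              x$kind, ep[1], ep[2], x$rest_length * 1e9, x$stiffness,
              if (is.null(x$gate)) "" else ", gated"))
  invisible(x)
}

#' Tabular export of the bundle geometry
#'
#' @param bundle Result of [build_bundle()].
#' @return A data frame with one line per Lagrangian point: `boundary_id`,
#'   `point`, `x`, `y`, `diameter`, `anchored`.
#' @export
geometry_table <- function(bundle) {
  do.call(rbind, lapply(bundle$rows, function(r) {
    data.frame(boundary_id = r$boundary_id, point = seq_len(nrow(r$X)),
               x = r$X[, 1], y = r$X[, 2], diameter = r$local_diameters,
               anchored = r$anchored, row.names = NULL)
  }))
}
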