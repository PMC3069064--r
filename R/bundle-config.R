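#' Bundle and domain configuration
#'
#' Collects every geometric parameter of the three-row inner hair cell (IHC)
#' stereocilia bundle and of the rectangular fluid domain it sits in. The
#' domain is the subtectorial space: the reticular lamina (RL) is the bottom
#' boundary, the underside of the tectorial membrane (TM) the top boundary.
#' The tallest row height is always `gap_height - tm_clearance`, so widening
#' the gap while keeping the rows fixed is expressed by enlarging both
#' `gap_height` and `tm_clearance` by the same amount.
#'
#' Row height ratios and stereocilia diameters are reconstructions: they are
#' not printed in the sources this model is based on, and are exposed here as
#' plain configuration knobs. The default inter-row spacing is chosen so that
#' the tip-link attachment geometry (shorter row's tip point to the taller
#' row's point one Lagrangian spacing higher) realizes the 170 nm tip-link
#' rest length exactly: `sqrt(170^2 - 75^2)` nm.
#'
#' @param domain_length Length of the fluid rectangle (m). Default 20 um.
#' @param gap_height RL-to-TM distance (m). Default 5 um.
#' @param tm_clearance Clearance between the tallest row tip and the TM (m).
#'   Default 0.5 um.
#' @param lagrangian_spacing Resting distance `r0` between consecutive
#'   Lagrangian points (m). Default 75 nm.
#' @param base_fraction Fraction of each stereocilium height occupied by the
#'   linearly tapered base. Default 1/3.
#' @param shaft_diameter,base_diameter Stereocilium diameters (m) along the
#'   shaft and at the basal insertion. Defaults 200 nm and 400 nm.
#' @param row_height_ratios Heights of the three rows relative to the tallest
#'   (tallest first, strictly decreasing). Default `c(1, 0.65, 0.35)`.
#' @param inter_row_spacing Horizontal distance between adjacent row axes (m).
#'   Default `sqrt(170e-9^2 - lagrangian_spacing^2)`.
#' @param tip_link_rest_length Tip-link rest length (m). Default 170 nm.
#' @param n_top_connectors Total number of horizontal top connectors (3 per
#'   adjacent-row pair). Default 6.
#' @param bundle_center_x Horizontal position of the middle row axis (m).
#'   Defaults to the middle of the domain.
#'
#' @return An object of class `bundle_config` (a validated named list).
#' @export
#' @examples
#' cfg <- bundle_config()
#' cfg$tallest_height   # 4.5e-06
bundle_config <- function(domain_length = 20e-6,
                          gap_height = 5e-6,
                          tm_clearance = 0.5e-6,
                          lagrangian_spacing = 75e-9,
                          base_fraction = 1 / 3,
                          shaft_diameter = 200e-9,
                          base_diameter = 400e-9,
                          row_height_ratios = c(1, 0.65, 0.35),
                          inter_row_spacing = NULL,
                          tip_link_rest_length = 170e-9,
                          n_top_connectors = 6L,
                          bundle_center_x = NULL) {
  if (is.null(inter_row_spacing)) {
    inter_row_spacing <- sqrt(tip_link_rest_length^2 - lagrangian_spacing^2)
  }
  if (is.null(bundle_center_x)) bundle_center_x <- domain_length / 2
  cfg <- list(
    domain_length = domain_length,
    gap_height = gap_height,
    tm_clearance = tm_clearance,
    lagrangian_spacing = lagrangian_spacing,
    base_fraction = base_fraction,
    shaft_diameter = shaft_diameter,
    base_diameter = base_diameter,
    row_height_ratios = row_height_ratios,
    inter_row_spacing = inter_row_spacing,
    tip_link_rest_length = tip_link_rest_length,
    n_top_connectors = as.integer(n_top_connectors),
    bundle_center_x = bundle_center_x
  )
  cfg$tallest_height <- gap_height - tm_clearance
  class(cfg) <- "bundle_config"
  validate_bundle_config(cfg)
  cfg
}

validate_bundle_config <- function(cfg) {
  lens <- c(
    domain_length = cfg$domain_length, gap_height = cfg$gap_height,
    tm_clearance = cfg$tm_clearance, lagrangian_spacing = cfg$lagrangian_spacing,
    shaft_diameter = cfg$shaft_diameter, base_diameter = cfg$base_diameter,
    inter_row_spacing = cfg$inter_row_spacing,
    tip_link_rest_length = cfg$tip_link_rest_length
  )
  bad <- names(lens)[!is.finite(lens) | lens <= 0]
  if (length(bad)) {
    stop("bundle_config: lengths must be positive, violated by: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (cfg$tallest_height <= 0) {
    stop("bundle_config: gap_height - tm_clearance (tallest row height) ",
         "must be positive", call. = FALSE)
  }
  r <- cfg$row_height_ratios
  if (length(r) != 3 || r[1] != 1 || any(diff(r) >= 0) || any(r <= 0)) {
    stop("bundle_config: row_height_ratios must be three strictly decreasing ",
         "positive values with the tallest equal to 1", call. = FALSE)
  }
  heights <- cfg$tallest_height * r
  nseg <- heights / cfg$lagrangian_spacing
  if (any(abs(nseg - round(nseg)) > 1)) {
    stop("bundle_config: lagrangian_spacing must divide each row height to ",
         "within one point spacing", call. = FALSE)
  }
  if (cfg$base_fraction <= 0 || cfg$base_fraction >= 1) {
    stop("bundle_config: base_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$n_top_connectors != 6L) {
    stop("bundle_config: the three-row bundle carries six horizontal top ",
         "connectors (3 per adjacent-row pair)", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.bundle_config <- function(x, ...) {
  cat("<bundle_config>\n")
  cat(sprintf("  domain: %.1f x %.1f um, TM clearance %.2f um\n",
              x$domain_length * 1e6, x$gap_height * 1e6, x$tm_clearance * 1e6))
  cat(sprintf("  rows: heights %s um (ratios %s)\n",
              paste(signif(x$tallest_height * x$row_height_ratios * 1e6, 3),
                    collapse = "/"),
              paste(x$row_height_ratios, collapse = ":")))
  cat(sprintf("  r0 = %.0f nm, inter-row spacing %.1f nm, tip link %.0f nm\n",
              x$lagrangian_spacing * 1e9, x$inter_row_spacing * 1e9,
              x$tip_link_rest_length * 1e9))
  invisible(x)
}
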