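#' Orbital reticular-lamina drive signal
#'
#' Parametric stand-in for the measured orbital reticular-lamina (RL) motion
#' at 200 Hz and 98 dB SPL. The phase convention fixes the signs: at drive
#' phase `theta = 180` degrees the RL is displaced maximally to the right
#' and downward, so `displacement_x = -A_h cos(theta)` and
#' `displacement_y = +A_v cos(theta)` (clockwise sense; counter-clockwise
#' flips the vertical sign). Amplitudes are calibration knobs: the
#' user-facing calibration procedure is to match the horizontal amplitude
#' and phase of the tallest row against a measured preparation.
#'
#' @param frequency Drive frequency (Hz). Default 200.
#' @param amp_h Horizontal displacement amplitude (m). Default 25 nm.
#' @param amp_v Vertical displacement amplitude (m). Default 5 nm (chosen so
#'   a free-end doubling of the forced-end displacement corresponds to a
#'   10 nm length change).
#' @param orbit `"cw"` or `"ccw"` orbit sense.
#' @param spl_label Text label of the sound-pressure level the amplitudes
#'   emulate.
#' @return An object of class `drive_signal`.
#' @export
drive_signal <- function(frequency = 200, amp_h = 25e-9, amp_v = 5e-9,
                         orbit = c("cw", "ccw"), spl_label = "98 dB") {
  orbit <- match.arg(orbit)
  stopifnot(frequency > 0, amp_h >= 0, amp_v >= 0)
  structure(list(frequency = frequency, amp_h = amp_h, amp_v = amp_v,
                 orbit = orbit, spl_label = spl_label,
                 omega = 2 * pi * frequency),
            class = "drive_signal")
}

# raised-cosine start-up ramp over the first half cycle and its derivative;
# enforces a start from rest (zero displacement AND zero velocity at t = 0)
ramp_factor <- function(t, drive, n_ramp_cycles = 0.5) {
  t_ramp <- n_ramp_cycles / drive$frequency
  r <- ifelse(t >= t_ramp, 1, 0.5 * (1 - cos(pi * t / t_ramp)))
  rdot <- ifelse(t >= t_ramp, 0, 0.5 * pi / t_ramp * sin(pi * t / t_ramp))
  list(r = r, rdot = rdot)
}

#' Reticular lamina motion
#'
#' Displacement and exact-velocity of the bottom wall at time `t`, with a
#' half-cycle raised-cosine ramp multiplying the signal so the flow starts
#' from rest.
#'
#' @param t Time (s). Vectorized.
#' @param drive A [drive_signal()].
#' @param ramp Apply the start-up ramp. Default `TRUE`.
#' @return List of vectors: `disp_x`, `disp_y`, `vel_x`, `vel_y`, and the
#'   drive phase `theta` (degrees, unwrapped).
#' @export
rl_motion <- function(t, drive, ramp = TRUE) {
  w <- drive$omega
  sgn_v <- if (drive$orbit == "cw") 1 else -1
  base_x <- -drive$amp_h * cos(w * t)
  base_y <- sgn_v * drive$amp_v * cos(w * t)
  dbase_x <- drive$amp_h * w * sin(w * t)
  dbase_y <- -sgn_v * drive$amp_v * w * sin(w * t)
  if (ramp) {
    rf <- ramp_factor(t, drive)
    list(disp_x = rf$r * base_x, disp_y = rf$r * base_y,
         vel_x = rf$r * dbase_x + rf$rdot * base_x,
         vel_y = rf$r * dbase_y + rf$rdot * base_y,
         theta = (w * t) * 180 / pi)
  } else {
    list(disp_x = base_x, disp_y = base_y, vel_x = dbase_x, vel_y = dbase_y,
         theta = (w * t) * 180 / pi)
  }
}

#' Tectorial membrane motion
#'
#' The top wall is horizontally stationary and follows the vertical RL
#' motion exactly, so the gap height never changes.
#'
#' @inheritParams rl_motion
#' @return List with `vel_x` (always 0) and `vel_y` (equal to the RL
#'   vertical velocity).
#' @export
tm_motion <- function(t, drive, ramp = TRUE) {
  rl <- rl_motion(t, drive, ramp = ramp)
  list(vel_x = 0 * rl$vel_y, vel_y = rl$vel_y)
}

#' Analytic side boundary profile (oscillatory Stokes channel flow)
#'
#' Horizontal velocity of the no-bundle channel flow driven by the
#' oscillatory motion of the bottom wall with the top wall fixed:
#' `u(y, t) = Re[ U_hat e^{i w t} sinh(k (H - y)) / sinh(k H) ]` with
#' `k = sqrt(i w / nu)`. Matches the bottom-wall horizontal velocity at
#' `y = 0` and vanishes at `y = H`; in the large-viscosity limit it reduces
#' to a linear Couette profile. The start-up ramp is applied as a
#' multiplicative factor.
#'
#' @param y Heights (m), in `[0, gap]`. Vectorized.
#' @param t Time (s), scalar.
#' @param drive A [drive_signal()].
#' @param props A [fluid_props()].
#' @param gap Channel height H (m).
#' @param ramp Apply the start-up ramp. Default `TRUE`.
#' @return Horizontal velocities at `y` (m/s).
#' @export
side_bc <- function(y, t, drive, props, gap, ramp = TRUE) {
  if (any(y < -1e-12 | y > gap + 1e-12)) {
    stop("side_bc: heights must lie within [0, gap]", call. = FALSE)
  }
  w <- drive$omega
  k <- sqrt(1i * w / props$nu)
  U_hat <- -1i * drive$amp_h * w  # so Re[U_hat e^{iwt}] = A_h w sin(wt)
  prof <- Re(U_hat * exp(1i * w * t) * sinh(k * (gap - y)) / sinh(k * gap))
  if (ramp) prof <- prof * ramp_factor(t, drive)$r
  prof
}

#' Assemble a named simulation scenario
#'
#' The three study conditions: `"normal"` (5 um gap, orbital drive),
#' `"widened_gap"` (gap widened by 5 um, everything else identical) and
#' `"horizontal_only"` (vertical drive amplitude zero, everything else
#' identical). The time step is 1/1000th of the drive period.
#'
#' @param name Scenario name.
#' @param n_cycles Total simulated drive cycles. Default 4.
#' @param n_transient_cycles Cycles discarded before analysis. Default 2.
#' @param resolution `"full"` (h = 78.125 nm), `"half"` or `"quarter"`.
#' @param drive A [drive_signal()]; fields are overridden per scenario.
#' @param bundle A [bundle_config()] for the normal gap; the widened variant
#'   is derived from it.
#' @param gate A [gate_state()] shared by both tip links.
#' @param props A [fluid_props()].
#' @param theta Viscous implicitness of the solver.
#' @param stokes Drop advection.
#' @param snapshot_phases Drive phases (degrees) at which full field
#'   snapshots are stored, each cycle.
#' @return An object of class `scenario`.
#' @export
make_scenario <- function(name = c("normal", "widened_gap", "horizontal_only"),
                          n_cycles = 4L, n_transient_cycles = 2L,
                          resolution = c("quarter", "half", "full"),
                          drive = drive_signal(),
                          bundle = bundle_config(),
                          gate = gate_state(),
                          props = fluid_props(),
                          theta = 0.5, stokes = FALSE,
                          snapshot_phases = seq(0, 315, by = 45)) {
  if (!is.character(name) || !name[1] %in%
        c("normal", "widened_gap", "horizontal_only")) {
    stop("make_scenario: unknown scenario '", name[1],
         "'; valid names: normal, widened_gap, horizontal_only",
         call. = FALSE)
  }
  name <- name[1]
  resolution <- match.arg(resolution)
  if (name == "widened_gap") {
    widen <- 5e-6
    bundle <- bundle_config(
      domain_length = bundle$domain_length,
      gap_height = bundle$gap_height + widen,
      tm_clearance = bundle$tm_clearance + widen,
      lagrangian_spacing = bundle$lagrangian_spacing,
      base_fraction = bundle$base_fraction,
      shaft_diameter = bundle$shaft_diameter,
      base_diameter = bundle$base_diameter,
      row_height_ratios = bundle$row_height_ratios,
      inter_row_spacing = bundle$inter_row_spacing,
      tip_link_rest_length = bundle$tip_link_rest_length,
      n_top_connectors = bundle$n_top_connectors,
      bundle_center_x = bundle$bundle_center_x
    )
  }
  if (name == "horizontal_only") {
    drive <- drive_signal(frequency = drive$frequency, amp_h = drive$amp_h,
                          amp_v = 0, orbit = drive$orbit,
                          spl_label = drive$spl_label)
  }
  fac <- switch(resolution, full = 1L, half = 2L, quarter = 4L)
  nx <- 256L %/% fac
  ny_per_5um <- 64L %/% fac
  ny <- as.integer(round(ny_per_5um * bundle$gap_height / 5e-6))
  structure(list(
    name = name, drive = drive, bundle = bundle, gate = gate, props = props,
    gap_height = bundle$gap_height,
    dt = 1 / drive$frequency / 1000,
    n_cycles = as.integer(n_cycles),
    n_transient_cycles = as.integer(n_transient_cycles),
    resolution = resolution, nx = nx, ny = ny,
    theta = theta, stokes = stokes,
    snapshot_phases = snapshot_phases
  ), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(paste0("<scenario '%s'>: gap %.1f um, %g Hz, A_h %.0f nm, ",
                     "A_v %.0f nm, %d cycles (%d transient), %s resolution ",
                     "(%d x %d)\n"),
              x$name, x$gap_height * 1e6, x$drive$frequency,
              x$drive$amp_h * 1e9, x$drive$amp_v * 1e9, x$n_cycles,
              x$n_transient_cycles, x$resolution, x$nx, x$ny))
  invisible(x)
}
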