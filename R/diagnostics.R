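#' Tip-link stretch and tension versus drive phase
#'
#' Extracts, for each gated tip link, the per-step signed stretch (current
#' length minus the closed-gate rest length, so compression is negative and
#' the open-gate increment is tracked separately), the signed tension and
#' the gate state over the analyzed (post-transient) cycles.
#'
#' @param rec A [run_simulation()] record.
#' @return Named list of data frames (`phase` in degrees within the cycle,
#'   `theta_unwrapped`, `stretch_nm`, `tension`, `gate_open`), one per tip
#'   link, of class `tip_link_trace`.
#' @export
tip_link_trace <- function(rec) {
  scen <- rec$scenario
  keep <- rec$theta > scen$n_transient_cycles * 360 + 1e-9
  if (!any(keep)) {
    stop("tip_link_trace: no steady (post-transient) cycle available",
         call. = FALSE)
  }
  out <- lapply(colnames(rec$stretch), function(nm) {
    data.frame(
      phase = rec$theta[keep] %% 360,
      theta_unwrapped = rec$theta[keep],
      stretch_nm = rec$stretch[keep, nm] * 1e9,
      tension = rec$tension[keep, nm],
      gate_open = rec$gate_open[keep, nm]
    )
  })
  names(out) <- colnames(rec$stretch)
  class(out) <- "tip_link_trace"
  out
}

#' Phase of the cycle maximum of a trace
#'
#' Quadratic interpolation of the maximum of `value` against the unwrapped
#' phase, reported as a wrapped drive phase in degrees.
#'
#' @param phase Unwrapped phase (degrees).
#' @param value Trace values.
#' @return Phase of the interpolated maximum, in `[0, 360)`.
#' @export
peak_phase <- function(phase, value) {
  i <- which.max(value)
  if (i > 1 && i < length(value)) {
    y1 <- value[i - 1]; y2 <- value[i]; y3 <- value[i + 1]
    denom <- y1 - 2 * y2 + y3
    shift <- if (abs(denom) > 0) 0.5 * (y1 - y3) / denom else 0
    shift <- max(-1, min(1, shift))
    ph <- phase[i] + shift * mean(diff(phase[max(1, i - 1):min(length(phase), i + 1)]))
  } else {
    ph <- phase[i]
  }
  ph %% 360
}

#' Tip-link synchronization summary
#'
#' Peak phases (quadratically interpolated) of the two tip-link stretch
#' traces over the analyzed cycles, and the phase of their joint maximum
#' (the maximum of the summed stretch trace, which reduces to the common
#' peak phase when the two links are synchronized).
#'
#' @param rec A [run_simulation()] record.
#' @return List with `peak_phase` (named, per link), `joint_peak_phase`,
#'   `peak_stretch_nm`, `min_stretch_nm` and `peak_tension` per link.
#' @export
tip_link_sync <- function(rec) {
  tr <- tip_link_trace(rec)
  pk <- vapply(tr, function(t) peak_phase(t$theta_unwrapped, t$stretch_nm),
               numeric(1))
  total <- Reduce(`+`, lapply(tr, function(t) t$stretch_nm))
  list(
    peak_phase = pk,
    joint_peak_phase = peak_phase(tr[[1]]$theta_unwrapped, total),
    peak_stretch_nm = vapply(tr, function(t) max(t$stretch_nm), numeric(1)),
    min_stretch_nm = vapply(tr, function(t) min(t$stretch_nm), numeric(1)),
    peak_tension = vapply(tr, function(t) max(t$tension), numeric(1))
  )
}

#' Row kinematics summary
#'
#' Cycle-peak absolute rotation and arclength change per row over the
#' analyzed cycles, plus the three-row average of the peak length change
#' and the middle/tallest rotation ratio.
#'
#' @param rec A [run_simulation()] record.
#' @return List with `peak_rotation_rad`, `peak_length_change_nm` (named by
#'   row), `mean_peak_length_change_nm` and `rotation_ratio_middle_tallest`.
#' @export
row_kinematics_summary <- function(rec) {
  rk <- row_kinematics(rec)
  rot <- vapply(rk, function(k) max(abs(k$rotation_rad)), numeric(1))
  len <- vapply(rk, function(k) max(abs(k$length_change_nm)), numeric(1))
  list(peak_rotation_rad = rot,
       peak_length_change_nm = len,
       mean_peak_length_change_nm = mean(len),
       rotation_ratio_middle_tallest = rot[["middle"]] / rot[["tallest"]])
}

#' Per-row rotation and length-change kinematics
#'
#' Rotation is the angle of the base-to-tip chord relative to its rest
#' orientation (translation invariant, hence identical in the lab and
#' reticular-lamina frames); the length change is the change of the row
#' chain's arclength. A rigid translation of a row therefore yields exactly
#' zero for both.
#'
#' @param rec A [run_simulation()] record.
#' @param analyzed_only Restrict to post-transient cycles. Default `TRUE`.
#' @return List of data frames per row (`phase`, `rotation_rad`,
#'   `length_change_nm`, `chord_change_nm`), class `row_kinematics`.
#' @export
row_kinematics <- function(rec, analyzed_only = TRUE) {
  asm <- rec$assembly
  keep <- if (analyzed_only) {
    rec$theta > rec$scenario$n_transient_cycles * 360 + 1e-9
  } else rep(TRUE, length(rec$theta))
  if (!any(keep)) {
    stop("row_kinematics: no steady cycle available", call. = FALSE)
  }
  steps <- which(keep)
  out <- list()
  for (k in seq_along(asm$rows)) {
    idx <- asm$offset[k] + seq_len(asm$n_per[k])
    X0 <- rec$rest_positions[idx, , drop = FALSE]
    chord0 <- X0[nrow(X0), ] - X0[1, ]
    ang0 <- atan2(chord0[2], chord0[1])
    arc0 <- sum(sqrt(rowSums((X0[-1, , drop = FALSE] -
                                X0[-nrow(X0), , drop = FALSE])^2)))
    rot <- len <- chd <- numeric(length(steps))
    for (s in seq_along(steps)) {
      Xs <- rec$positions[idx, , steps[s]]
      chord <- Xs[nrow(Xs), ] - Xs[1, ]
      dang <- atan2(chord[2], chord[1]) - ang0
      rot[s] <- atan2(sin(dang), cos(dang))
      len[s] <- sum(sqrt(rowSums((Xs[-1, , drop = FALSE] -
                                    Xs[-nrow(Xs), , drop = FALSE])^2))) - arc0
      chd[s] <- sqrt(sum(chord^2)) - sqrt(sum(chord0^2))
    }
    out[[names(asm$rows)[k]]] <- data.frame(
      phase = rec$theta[steps] %% 360, theta_unwrapped = rec$theta[steps],
      rotation_rad = rot, length_change_nm = len * 1e9,
      chord_change_nm = chd * 1e9)
  }
  class(out) <- "row_kinematics"
  out
}

#' Detect closed-streamline eddies in a flow snapshot
#'
#' Candidate vortex centers are strict local extrema of the vorticity field;
#' a candidate counts as an eddy when, inside a sub-micron window around it,
#' the streamfunction evaluated in the frame moving with the local mean flow
#' attains its window extremum strictly inside (the center value exceeds or
#' falls below every window-boundary value), which is exactly the condition
#' for a closed streamfunction contour around the candidate. Pure shear
#' (open streamlines, constant vorticity) yields no detections, and the
#' criterion is invariant under superposition of a uniform flow.
#'
#' @param omega Vorticity at cell corners ((nx+1) x (ny+1)).
#' @param u,v MAC velocity arrays the snapshot was taken from.
#' @param grid An [eulerian_grid()].
#' @param window Window half-size (m). Default 0.5 um (sub-micron window).
#' @param rel_floor Relative vorticity floor below which extrema are
#'   ignored, as a fraction of the field maximum.
#' @return A `vortex_report` data frame: `x`, `y`, `peak_vorticity`,
#'   `circulation_sign`; window and criterion recorded as attributes.
#' @export
detect_vortices <- function(omega, u, v, grid, window = 0.5e-6,
                            rel_floor = 1e-6) {
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  psi <- streamfunction(u, v, grid)
  floor_abs <- rel_floor * max(abs(omega), 1e-300)
  hits <- NULL
  wcells <- max(2L, as.integer(round(window / h)))
  for (i in 2:nx) {
    for (j in 2:ny) {
      w0 <- omega[i, j]
      nb <- omega[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (abs(w0) < floor_abs) next
      is_max <- w0 > max(nb[-5]) + 0
      is_min <- w0 < min(nb[-5])
      if (!is_max && !is_min) next
      i0 <- max(1L, i - wcells); i1 <- min(nx + 1L, i + wcells)
      j0 <- max(1L, j - wcells); j1 <- min(ny + 1L, j + wcells)
      # local mean flow over the window (cell-centered averages)
      um <- mean(u[max(1, i0 - 1):min(nx + 1, i1), max(1, j0):min(ny, j1 - 1)])
      vm <- mean(v[max(1, i0):min(nx, i1 - 1), max(1, j0):min(ny + 1, j1)])
      xs <- (i0:i1 - 1) * h
      ys <- (j0:j1 - 1) * h
      psi_loc <- psi[i0:i1, j0:j1] -
        outer(xs, ys, function(x, y) um * y - vm * x)
      pc <- psi_loc[i - i0 + 1L, j - j0 + 1L]
      ring <- c(psi_loc[1, ], psi_loc[nrow(psi_loc), ],
                psi_loc[, 1], psi_loc[, ncol(psi_loc)])
      closed <- pc > max(ring) || pc < min(ring)
      if (closed) {
        hits <- rbind(hits, data.frame(
          x = (i - 1) * h, y = (j - 1) * h, peak_vorticity = w0,
          circulation_sign = sign(w0)))
      }
    }
  }
  if (is.null(hits)) {
    hits <- data.frame(x = numeric(0), y = numeric(0),
                       peak_vorticity = numeric(0),
                       circulation_sign = numeric(0))
  } else {
    # merge detections closer than half a window (same eddy)
    keep <- rep(TRUE, nrow(hits))
    ord <- order(-abs(hits$peak_vorticity))
    for (a in ord) {
      if (!keep[a]) next
      d <- sqrt((hits$x - hits$x[a])^2 + (hits$y - hits$y[a])^2)
      drop <- which(d < window / 2 & seq_len(nrow(hits)) != a & keep)
      keep[drop] <- FALSE
    }
    hits <- hits[keep, , drop = FALSE]
    rownames(hits) <- NULL
  }
  attr(hits, "criterion") <- list(window = window, rel_floor = rel_floor,
                                  frame = "local mean flow removed")
  class(hits) <- c("vortex_report", class(hits))
  hits
}

#' Nanovortex experiment: sudden gating-spring elongation in the normal run
#'
#' Runs the normal scenario with a scheduled gate opening at the
#' peak-tension drive phase and the elongation applied as a prescribed
#' sub-micron boundary motion (an impulsively moved plate), then searches
#' the flow snapshot taken at the elongation step for closed-streamline
#' eddies within the detection window of the opened gate. The background
#' printed gating threshold can never fire at piconewton link tensions, so
#' the event is scheduled rather than tension-triggered.
#'
#' @param open_phase Drive phase (degrees of the first analyzed cycle) at
#'   which the gate opens. Default 180 (the phase of peak tip-link stretch;
#'   the ensuing quarter cycle is searched).
#' @param which_link Gate to open (`"lower_tip_link"` carries the gating
#'   spring at the lower end; the upper link is also allowed).
#' @param resolution Grid resolution of the run.
#' @param n_cycles,n_transient_cycles Run length; the default stops shortly
#'   after the event.
#' @param window Detection window half-size (m) around the gate.
#' @return List with the `run_record`, the `vortex_report` restricted to
#'   the window, the gate position, and the full-field report.
#' @export
nanovortex_experiment <- function(open_phase = 180,
                                  which_link = "lower_tip_link",
                                  resolution = "quarter",
                                  n_cycles = 3L, n_transient_cycles = 2L,
                                  window = 1e-6) {
  gate <- gate_state(mode = "scheduled", scheduled_phase = open_phase,
                     elongation_mode = "prescribed")
  scen <- make_scenario("normal", n_cycles = n_cycles,
                        n_transient_cycles = n_transient_cycles,
                        resolution = resolution, gate = gate)
  rec <- run_simulation(scen)
  ev <- rec$gate_events[rec$gate_events$link == which_link, , drop = FALSE]
  if (nrow(ev) == 0) {
    # both gates share the schedule; fall back to whichever fired
    ev <- rec$gate_events
  }
  if (nrow(ev) == 0) stop("nanovortex_experiment: no gate-opening event",
                          call. = FALSE)
  snap_i <- which(vapply(rec$snapshots, function(s) s$event == "gate_opening",
                         logical(1)))[1]
  if (is.na(snap_i)) stop("nanovortex_experiment: no event snapshot",
                          call. = FALSE)
  snap <- rec$snapshots[[snap_i]]
  # position of the opened gate (lower end of the link) at the event
  lk <- rec$assembly$links[[ev$link[1]]]
  ab <- resolve_link(lk, rec$assembly$rows)
  gate_pos <- ab$a
  rep_all <- detect_vortices(snap$omega, snap$u, snap$v, rec$grid,
                             window = window / 2)
  near <- rep_all[sqrt((rep_all$x - gate_pos[1])^2 +
                         (rep_all$y - gate_pos[2])^2) <= window, ,
                  drop = FALSE]
  list(record = rec, report = near, gate_position = gate_pos,
       full_report = rep_all, snapshot_phase = snap$theta)
}

#' Rayleigh vorticity of a suddenly elongating gating spring
#'
#' Vorticity scale of an impulsively started plate: speed `A / tau_o` over
#' the viscous diffusion depth `sqrt(pi nu tau_o)`, i.e.
#' `omega = (A / tau_o) / sqrt(pi nu tau_o)`.
#'
#' @param A Elongation (m), e.g. the 5 nm gate extension.
#' @param nu Kinematic viscosity (m^2/s).
#' @param tau_o Elongation time (s).
#' @return Vorticity estimate (1/s).
#' @export
rayleigh_vorticity <- function(A, nu, tau_o) {
  stopifnot(A > 0, nu > 0, tau_o > 0)
  (A / tau_o) / sqrt(pi * nu * tau_o)
}

#' Order-of-magnitude calcium transport estimates
#'
#' Closed-form rates around the tip-link channel: the diffusive supply rate
#' `D / l^2` and its reciprocal time, the calcium ion influx implied by a
#' total transduction current with a concentration-proportional carrier
#' split between Ca2+ (divalent) and K+ (monovalent), and the critical
#' gating-spring elongation time `tau_crit` at which the Rayleigh vorticity
#' timescale matches the diffusion time (`1/omega(tau) = l^2/D`), below
#' which vortical convection can augment diffusion.
#'
#' The influx figure is an order-of-magnitude estimate by construction: it
#' assumes the calcium share of the current is simply proportional to its
#' concentration among the carriers.
#'
#' @param D Ca2+ diffusivity (m^2/s). Default 4e-10 (4e-6 cm^2/s).
#' @param l Tip-link length (m). Default 170 nm.
#' @param I_total Total transduction current (A). Default 500 pA.
#' @param ca_conc,k_conc Endolymph Ca2+ and K+ concentrations (mol/L).
#'   Defaults 20 uM and 160 mM.
#' @param A Gating-spring elongation (m). Default 5 nm.
#' @param nu Kinematic viscosity (m^2/s). Default 0.7e-6.
#' @return An object of class `transport_estimates`.
#' @export
transport_estimates <- function(D = 4e-10, l = 170e-9, I_total = 500e-12,
                                ca_conc = 20e-6, k_conc = 160e-3,
                                A = 5e-9, nu = 0.7e-6) {
  stopifnot(D > 0, l > 0, I_total >= 0, ca_conc > 0, k_conc > 0)
  e <- 1.602176634e-19
  diffusion_rate <- D / l^2
  diffusion_time <- l^2 / D
  x_ca <- ca_conc / (ca_conc + k_conc)
  influx_rate <- I_total * x_ca / (2 * e)
  # (A/tau)/sqrt(pi nu tau) = D/l^2  =>  tau^(3/2) = A l^2 / (D sqrt(pi nu))
  tau_crit <- (A / (diffusion_rate * sqrt(pi * nu)))^(2 / 3)
  structure(list(diffusivity = D, tip_link_length = l,
                 diffusion_rate = diffusion_rate,
                 diffusion_time = diffusion_time,
                 ca_influx_rate = influx_rate,
                 ca_current_fraction = x_ca,
                 tau_crit = tau_crit),
            class = "transport_estimates")
}

#' @export
print.transport_estimates <- function(x, ...) {
  cat("<transport_estimates>\n")
  cat(sprintf("  diffusive supply rate D/l^2 : %.3g /s\n", x$diffusion_rate))
  cat(sprintf("  diffusion time l^2/D        : %.3g s\n", x$diffusion_time))
  cat(sprintf("  Ca2+ influx (order of magnitude, concentration split): %.3g /s\n",
              x$ca_influx_rate))
  cat(sprintf("  critical elongation time tau_crit: %.3g s\n", x$tau_crit))
  invisible(x)
}
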