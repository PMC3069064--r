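# Shared fixtures: scenario runs are expensive, so each named run is
# computed once per test session and reused across test files.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(name, resolution = "quarter") {
  key <- paste(name, resolution, sep = "_")
  if (is.null(.run_cache[[key]])) {
    scen <- make_scenario(name, resolution = resolution)
    .run_cache[[key]] <- suppressMessages(run_simulation(scen))
  }
  .run_cache[[key]]
}

cached_nanovortex <- function() {
  if (is.null(.run_cache[["nanovortex"]])) {
    .run_cache[["nanovortex"]] <-
      suppressMessages(nanovortex_experiment(resolution = "quarter"))
  }
  .run_cache[["nanovortex"]]
}

cached_zero_drive <- function() {
  if (is.null(.run_cache[["zero_drive"]])) {
    scen <- make_scenario("normal", n_cycles = 1L, n_transient_cycles = 0L,
                          resolution = "quarter",
                          drive = drive_signal(amp_h = 0, amp_v = 0))
    .run_cache[["zero_drive"]] <- suppressMessages(run_simulation(scen))
  }
  .run_cache[["zero_drive"]]
}

# oscillating-wall channel flow against the analytic profile; returns the
# max abs error of the horizontal velocity profile at an interior column
channel_flow_error <- function(ny, steps_per_cycle, cycles = 1.5,
                               props = fluid_props(), drive = drive_signal()) {
  nx <- 8L
  H <- 5e-6
  g <- eulerian_grid(domain_length = nx * H / ny, gap_height = H,
                     nx = nx, ny = as.integer(ny))
  dt <- 1 / drive$frequency / steps_per_cycle
  sol <- fluid_solver(g, props, dt)
  st <- flow_state(g)
  bc_at <- function(t) {
    rl <- rl_motion(t, drive)
    prof <- side_bc(g$yu, t, drive, props, H)
    wall_bc(g, u_bottom = rl$vel_x, u_top = 0, v_wall = rl$vel_y,
            u_left = prof, u_right = prof, v_side = 0)
  }
  n <- as.integer(cycles * steps_per_cycle)
  for (k in seq_len(n)) st <- sol$step(st, bc_at((k - 1) * dt), bc_at(k * dt))
  ua <- side_bc(g$yu, n * dt, drive, props, H)
  list(err = max(abs(st$u[4, ] - ua)), scale = max(abs(ua)),
       divergence = st$divergence)
}

# minimal straight-chain boundary for force unit tests
straight_chain <- function(n, r0 = 75e-9, d = 200e-9, x0 = c(0, 0),
                           dir = c(0, 1)) {
  X <- cbind(x0[1] + dir[1] * r0 * (0:(n - 1)),
             x0[2] + dir[2] * r0 * (0:(n - 1)))
  ciliasim:::new_lagrangian_boundary(
    "chain", X, rep(r0, n - 1), rep(d, n), rep(FALSE, n))
}
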