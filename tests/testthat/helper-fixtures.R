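# shared test fixtures, built in code

# genome with permissive thresholds so a step stimulus propagates to the
# motor layer (used for latency and pipeline accounting)
permissive_genome <- function() {
  gv <- genome_values(default_genome())
  gv[["theta_int"]] <- 0.05
  gv[["theta_m"]] <- 0.2
  gv[["theta_b0"]] <- 0.05
  gv[["n_b"]] <- 1
  gv[["w_mitral_cortex"]] <- 0.5
  gv[["w_cortex_motor"]] <- 0.5
  gv[["u_sensor_mitral"]] <- 0
  gv[["u_mitral_inter"]] <- 0
  gv[["u_mitral_cortex"]] <- 0
  gv[["u_inter_cortex"]] <- 0
  gv[["u_cortex_motor"]] <- 0
  genome(gv)
}

# small circuit for fast stepping tests
tiny_config <- function(...) {
  network_config(n_cortex = 64, branches = 2, exc_per_branch = 4,
                 inh_per_branch = 1, n_sensors = 32, cluster_size = 4,
                 n_inter = 8, inter_fanin = 4, n_motor = 16,
                 motor_afferents = 16, ...)
}

# controller issuing a fixed current pair every step
scripted_controller <- function(I_L, I_R) {
  structure(list(reset = function() invisible(NULL),
                 step = function(concentrations, prox, n_substeps = 4L)
                   c(I_L, I_R),
                 kind = "scripted"),
            class = "pb_controller")
}

# a small still-air scenario for fast trial tests
mini_scenario <- function(max_duration = 3, proximity_radius = 0.1,
                          robot_x = 0.3, robot_y = 0.5, heading = 0,
                          source_cell = c(20, 13), ...) {
  scenario(
    grid = list(nx = 25, ny = 25, cell_size = 0.04, dt = 0.030,
                viscosity = 0, dye_diffusion = 0, evaporation_rate = 0,
                solver_iters = 8, n_channels = 1),
    sources = list(plume_source(source_cell, channel = 1, rate = 20)),
    odorants = list(odorant(c(1, rep(0, 9)), channel = 1)),
    robot_start = list(x = robot_x, y = robot_y, heading = heading),
    target_source = 1, proximity_radius = proximity_radius,
    max_duration = max_duration, warmup_steps = 0, seed = 1,
    name = "mini", ...
  )
}
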