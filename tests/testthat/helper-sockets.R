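# helpers for socket-coupling tests (shared with the acceptance suite)

# genome whose first motor firing produces a strict subset of active units,
# so the signed tread currents are nonzero at the first active timestep and
# the propagation latency is observable through the MOTOR messages
latency_genome <- function() {
  gv <- genome_values(default_genome())
  gv[["theta_int"]] <- 0.05
  gv[["n_b"]] <- 1
  gv[["w_sensor_mitral"]] <- 0.8
  gv[["psp_sensor_mitral"]] <- 1
  gv[["w_mitral_cortex"]] <- 0.5
  gv[["w_cortex_motor"]] <- 0.5
  gv[["theta_b0"]] <- 1.3
  gv[["theta_m"]] <- 5
  for (u in grep("^u_", names(gv), value = TRUE)) gv[[u]] <- 0
  gv
}

# serve a neural-controller brain in a background R process
start_brain_server <- function(port, steps_per_message, gv, seed,
                               odor_degrees = rep(1, 10)) {
  callr::r_bg(function(port, steps_per_message, gv, seed, odor_degrees) {
    library(plumebot)
    cfg <- network_config(n_cortex = 64, branches = 2, exc_per_branch = 4,
                          inh_per_branch = 1, n_sensors = 32,
                          cluster_size = 4, n_inter = 8, inter_fanin = 4,
                          n_motor = 16, motor_afferents = 16)
    net <- build_network(genome(gv), cfg, seed = seed,
                         homeostasis = FALSE)
    arr <- generate_sensor_array(n_sensors = cfg$n_sensors, seed = seed)
    od <- list(odorant(odor_degrees, channel = 1))
    ctrl <- neural_controller(net, arr, od, calibrate = FALSE)
    serve_brain(port, ctrl, steps_per_message = steps_per_message)
  }, args = list(port = port, steps_per_message = steps_per_message,
                 gv = gv, seed = seed, odor_degrees = odor_degrees))
}

connect_with_retry <- function(port, tries = 40) {
  for (k in seq_len(tries)) {
    ctrl <- tryCatch(suppressWarnings(socket_controller(port = port)),
                     error = function(e) NULL)
    if (!is.null(ctrl)) return(ctrl)
    Sys.sleep(0.25)
  }
  stop("could not connect to brain server on port ", port)
}
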