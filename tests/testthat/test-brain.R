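test_that("scaled-down build matches the direct counting oracle", {
  cfg <- network_config(n_cortex = 64, branches = 2, exc_per_branch = 4,
                        inh_per_branch = 1, n_sensors = 64,
                        cluster_size = 4, n_inter = 16, inter_fanin = 4,
                        n_motor = 16, motor_afferents = 32)
  net <- build_network(default_genome(), cfg, seed = 3)
  counts <- network_counts(net)
  expect_equal(counts$inputs_per_neuron, 2 * (4 + 1))
  expect_equal(counts$cortex_synapses, 64 * 2 * (4 + 1))
  expect_equal(length(net$wiring$cx_e_src), 64 * 2 * 4)
  expect_equal(length(net$wiring$mo_src), 16 * 32)
  expect_equal(counts$n_mitral, 16)
})

test_that("wiring is deterministic under the build seed", {
  cfg <- tiny_config()
  n1 <- build_network(default_genome(), cfg, seed = 7)
  n2 <- build_network(default_genome(), cfg, seed = 7)
  n3 <- build_network(default_genome(), cfg, seed = 8)
  expect_identical(n1$wiring, n2$wiring)
  expect_false(identical(n1$wiring, n3$wiring))
})

test_that("genome values out of bounds are rejected at build time", {
  gv <- genome_values(default_genome())
  gv[["n_b"]] <- 99
  expect_error(genome(gv), "bounds")
})

test_that("zero input propagates zero motor activity", {
  net <- build_network(default_genome(), tiny_config(), seed = 1)
  for (t in 1:20) {
    mo <- step_network(net, numeric(32))
    expect_true(all(mo == 0))
  }
  expect_error(step_network(net, rep(NaN, 32)), "non-finite")
})

test_that("a step stimulus reaches the motor layer in exactly five timesteps", {
  net <- build_network(permissive_genome(), tiny_config(), seed = 2,
                       homeostasis = FALSE)
  expect_identical(measure_latency(net), 5L)
  # stepwise accounting: motors silent through step 4, active at step 5
  reset_network(net)
  stim <- rep(1, 32)
  for (t in 1:4) expect_true(all(step_network(net, stim) == 0))
  expect_true(any(step_network(net, stim) > 0))
  # zero stimulus never propagates
  expect_identical(measure_latency(net, stimulus = numeric(32)),
                   NA_integer_)
})

test_that("removing the inhibition-alignment stage shortens the pipeline to four steps", {
  net <- build_network(permissive_genome(),
                       tiny_config(align_inhibition = FALSE),
                       seed = 2, homeostasis = FALSE)
  expect_identical(measure_latency(net), 4L)
})

test_that("depression resource follows the first-order algebra", {
  # U = 0: no depression, resource pinned at 1
  r <- apply_depression(1, 1, U = 0, r_rec = 0.1, w = 2)
  expect_equal(r$effective, 2)
  expect_equal(r$resources, 1)
  # pure recovery from depletion is geometric at rate (1 - r_rec)
  R <- 0.2
  for (k in 1:5) {
    prev_gap <- 1 - R
    R <- apply_depression(R, 0, U = 0.5, r_rec = 0.25)$resources
    expect_equal(1 - R, prev_gap * 0.75, tolerance = 1e-12)
  }
  # sustained activation: fixed point R* = r_rec / (r_rec + U - U * r_rec)
  U <- 0.37; rr <- 0.11
  R <- 1
  for (k in 1:400) R <- apply_depression(R, 1, U, rr)$resources
  expect_equal(R, rr / (rr + U - U * rr), tolerance = 1e-9)
})

test_that("depression resources stay in [0, 1] under arbitrary activity", {
  set.seed(14)
  R <- runif(50)
  for (k in 1:200) {
    a <- runif(50)
    U <- runif(1); rr <- runif(1)
    R <- apply_depression(R, a, U, rr)$resources
    expect_true(all(R >= 0 & R <= 1))
  }
  # and inside a stepping network driven with random input
  net <- build_network(default_genome(), tiny_config(), seed = 5)
  for (t in 1:100) step_network(net, runif(32))
  for (Rc in net$R) expect_true(all(Rc >= 0 & Rc <= 1))
})

test_that("network and pure-R depression rules agree (dual route)", {
  gv <- genome_values(permissive_genome())
  gv[["u_sensor_mitral"]] <- 0.4
  gv[["rec_sensor_mitral"]] <- 0.07
  gv[["psp_sensor_mitral"]] <- 1
  net <- build_network(genome(gv), tiny_config(), seed = 2,
                       homeostasis = FALSE)
  # the first timestep reads the zero sensor-hold buffer (pipeline stage),
  # so the reference sees one silent step followed by 29 active ones
  R_ref <- apply_depression(rep(1, 32), 0, 0.4, 0.07)$resources
  for (t in 1:30) {
    step_network(net, rep(1, 32))
    if (t > 1) R_ref <- apply_depression(R_ref, 1, 0.4, 0.07)$resources
  }
  expect_equal(net$R[[1]], R_ref, tolerance = 1e-12)
})

test_that("homeostatic updates move thresholds toward the target rate", {
  # equilibrium: average at target leaves the threshold unchanged
  h <- update_homeostasis(avg = 0.2, theta = 1, activity = 0.2,
                          target = 0.2)
  expect_equal(h$theta, 1)
  # disabled adaptation freezes thresholds
  h2 <- update_homeostasis(avg = 0.9, theta = 1, activity = 1,
                           target = 0.1, eta = 0)
  expect_equal(h2$theta, 1)
  # constant supra-threshold drive raises theta until the rate matches
  theta <- 0.05; avg <- 0.5
  drive <- 1
  rate_hist <- numeric(0)
  for (t in 1:20000) {
    act <- as.numeric(drive >= theta)
    st <- update_homeostasis(avg, theta, act, target = 0.2, eta = 5e-3)
    avg <- st$avg; theta <- st$theta
    # drive fluctuates so the unit can express intermediate rates
    drive <- stats::runif(1, 0, 2)
    if (t > 15000) rate_hist <- c(rate_hist, act)
  }
  expect_lt(abs(mean(rate_hist) - 0.2), 0.02)
})

test_that("homeostasis holds branch and soma rates near their targets in operation", {
  gv <- genome_values(permissive_genome())
  gv[["w_sensor_mitral"]] <- 0.8     # keep mitral activations graded
  gv[["psp_sensor_mitral"]] <- 1
  gv[["branch_target"]] <- 0.15
  gv[["soma_target"]] <- 0.2
  # thresholded mode: the homeostatic lever is the branch threshold
  net <- build_network(genome(gv), tiny_config(), seed = 6,
                       homeostasis = TRUE)
  set.seed(8)
  n_steps <- 8000
  br <- numeric(n_steps)
  for (t in seq_len(n_steps)) {
    step_network(net, runif(32))
    br[t] <- mean(net$drive_b >= net$theta_b)
  }
  late_branch <- mean(br[(n_steps - 3000):n_steps])
  expect_lt(abs(late_branch - 0.15), 0.20 * 0.15 + 0.02)
  # sigmoidal mode: the soma threshold is homeostatic as well (slower:
  # branch thresholds settle first, then the soma threshold tracks)
  net2 <- build_network(genome(gv),
                        tiny_config(branch_mode = "sigmoidal"),
                        seed = 6, homeostasis = TRUE)
  n_long <- 16000
  sr <- numeric(n_long)
  for (t in seq_len(n_long)) {
    step_network(net2, runif(32))
    sr[t] <- mean(net2$Cx)
  }
  late_soma <- mean(sr[(n_long - 4000):n_long])
  expect_lt(abs(late_soma - 0.2), 0.20 * 0.2 + 0.02)
})

test_that("branch activation implements the three dendritic modes", {
  expect_identical(branch_activation(0.5, "thresholded", theta = 0.5), 1)
  expect_identical(branch_activation(0.49, "thresholded", theta = 0.5), 0)
  expect_identical(branch_activation(0.37, "linear"), 0.37)
  expect_equal(branch_activation(0.8, "sigmoidal", theta = 0.8, gain = 4),
               0.5)
  expect_error(branch_activation(1, "quadratic"), "arg")
})

test_that("with depression off and homeostasis frozen the network is memory-bounded", {
  g <- permissive_genome()
  D_max <- max(genome_values(g)[paste0("psp_", c(
    "sensor_mitral", "mitral_inter", "mitral_cortex", "inter_cortex",
    "cortex_motor"))])
  window <- ceiling(D_max) + 5   # PSP memory plus pipeline depth
  cfg <- tiny_config()
  set.seed(31)
  shared <- lapply(seq_len(window), function(i) runif(32))
  run_tail <- function(prefix) {
    net <- build_network(g, cfg, seed = 4, homeostasis = FALSE)
    for (x in prefix) step_network(net, x)
    out <- NULL
    for (x in shared) out <- step_network(net, x)
    out
  }
  pre1 <- lapply(1:12, function(i) runif(32))
  pre2 <- lapply(1:20, function(i) runif(32))
  expect_identical(run_tail(pre1), run_tail(pre2))
})

test_that("threshold calibration brings branch firing near the target rate", {
  set.seed(40)
  gv <- genome_values(random_genome())
  gv[["branch_target"]] <- 0.2
  net <- build_network(genome(gv), tiny_config(), seed = 9)
  inp <- runif(32, 0.2, 0.6)
  calibrate_network(net, inp)
  set_homeostasis(net, FALSE)
  rates <- replicate(60, {
    step_network(net, inp)
    mean(net$drive_b >= net$theta_b)
  })
  expect_lt(abs(mean(rates[20:60]) - 0.2), 0.15)
})
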