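#' Structural configuration of the olfactorimotor circuit
#'
#' Defaults reproduce the full-scale architecture: 1,024 sensors pooled in
#' disjoint clusters of 4 by 256 mitral relay units; 256 feedforward
#' inhibitory interneurons; 4,096 cortical pyramidal neurons, each with 8
#' identical dendritic branches receiving 16 excitatory (mitral) and 4
#' inhibitory (interneuron) inputs, i.e. 160 afferents per neuron and
#' 655,360 cortical synapses in total; and 16 motor units each receiving 256
#' random cortical afferents.
#'
#' @param n_cortex Number of cortical pyramidal neurons.
#' @param branches Dendritic branches per cortical neuron.
#' @param exc_per_branch,inh_per_branch Excitatory/inhibitory inputs per
#'   branch.
#' @param n_sensors Sensor count (must be divisible by `cluster_size`).
#' @param cluster_size Sensors pooled per mitral unit.
#' @param n_inter Feedforward interneuron count.
#' @param inter_fanin Mitral inputs per interneuron.
#' @param n_motor Motor units.
#' @param motor_afferents Cortical afferents per motor unit.
#' @param branch_mode Dendritic integration mode: `"thresholded"` (branch
#'   fires at threshold, soma fires on a count of active branches),
#'   `"linear"` (unthresholded branch sums aggregated at the soma) or
#'   `"sigmoidal"` (logistic branch nonlinearity).
#' @param align_inhibition Delay the direct mitral->cortex path by one extra
#'   timestep so excitation and disynaptic feedforward inhibition arrive at
#'   cortex in the same stage (preserves the five-stage sensor->motor
#'   latency). Disable only for stage-accounting experiments.
#' @return A `network_config` list.
#' @export
network_config <- function(n_cortex = 4096, branches = 8,
                           exc_per_branch = 16, inh_per_branch = 4,
                           n_sensors = 1024, cluster_size = 4,
                           n_inter = 256, inter_fanin = 16,
                           n_motor = 16, motor_afferents = 256,
                           branch_mode = c("thresholded", "linear",
                                           "sigmoidal"),
                           align_inhibition = TRUE) {
  branch_mode <- match.arg(branch_mode)
  stopifnot(n_sensors %% cluster_size == 0,
            inter_fanin <= n_sensors / cluster_size,
            exc_per_branch <= n_sensors / cluster_size,
            inh_per_branch <= n_inter,
            motor_afferents <= n_cortex)
  structure(list(
    n_cortex = n_cortex, branches = branches,
    exc_per_branch = exc_per_branch, inh_per_branch = inh_per_branch,
    n_sensors = n_sensors, cluster_size = cluster_size,
    n_mitral = n_sensors %/% cluster_size,
    n_inter = n_inter, inter_fanin = inter_fanin,
    n_motor = n_motor, motor_afferents = motor_afferents,
    branch_mode = branch_mode, align_inhibition = align_inhibition
  ), class = "network_config")
}

#' Desk-scale circuit preset
#'
#' A reduced architecture (256 sensors, 64 mitral, 64 interneurons, 512
#' cortical neurons, 16 motor units) preserving all structural ratios, used
#' for closed-loop evolution at desk scale.
#'
#' @return A [network_config()].
#' @export
network_config_desk <- function() {
  network_config(n_cortex = 512, n_sensors = 256, n_inter = 64,
                 inter_fanin = 16, motor_afferents = 256)
}

# fixed homeostasis constants (adjustment rate, averaging time constant and
# threshold bounds are fixed; only the target rates are evolvable)
HOMEO_ETA <- 1e-3
HOMEO_TAU_AVG <- 200
HOMEO_THETA_MIN <- 1e-4
HOMEO_THETA_MAX <- 50

#' Build the layered olfactorimotor network
#'
#' Constructs wiring tables (deterministic under `seed`) and dynamic state
#' for the five-stage circuit. Parameter values come from a genome (see
#' [genome_schema()]): per-class synaptic weights, PSP durations, depression
#' fractions and recovery rates, homeostatic target rates, branch count to
#' fire the soma, and unit thresholds.
#'
#' The returned network is an environment: [step_network()] advances its
#' state in place. Rebuilding with the same genome and seed, or calling
#' [reset_network()], restores the identical initial state.
#'
#' @param genome A genome from [genome()] / [random_genome()], or a named
#'   numeric vector of parameter values.
#' @param config A [network_config()].
#' @param seed Integer wiring seed.
#' @param homeostasis Start with homeostatic threshold adjustment enabled.
#' @param wiring Optional precomputed wiring tables from a previous
#'   [build_network()] with the same `config` and `seed` (reused across the
#'   individuals of an evolution, whose wiring is shared).
#' @return A `network` environment.
#' @export
build_network <- function(genome, config = network_config(), seed = 1,
                          homeostasis = TRUE, wiring = NULL) {
  p <- genome_values(genome)
  cfgS <- config
  n_mitral <- cfgS$n_mitral
  if (is.null(wiring)) {
    with_seed(seed, {
      inter_src <- as.integer(unlist(lapply(seq_len(cfgS$n_inter), function(i)
        sample.int(n_mitral, cfgS$inter_fanin))) - 1L)
      n_branch <- cfgS$n_cortex * cfgS$branches
      cx_e_src <- as.integer(unlist(lapply(seq_len(n_branch), function(b)
        sample.int(n_mitral, cfgS$exc_per_branch))) - 1L)
      cx_i_src <- as.integer(unlist(lapply(seq_len(n_branch), function(b)
        sample.int(cfgS$n_inter, cfgS$inh_per_branch))) - 1L)
      mo_src <- as.integer(unlist(lapply(seq_len(cfgS$n_motor), function(m)
        sample.int(cfgS$n_cortex, cfgS$motor_afferents))) - 1L)
    })
    wiring <- list(inter_src = inter_src, cx_e_src = cx_e_src,
                   cx_i_src = cx_i_src, mo_src = mo_src)
  }
  w <- c(p[["w_sensor_mitral"]], p[["w_mitral_inter"]],
         p[["w_mitral_cortex"]], -abs(p[["w_inter_cortex"]]),
         p[["w_cortex_motor"]])
  D <- pmax(1L, as.integer(round(c(
    p[["psp_sensor_mitral"]], p[["psp_mitral_inter"]],
    p[["psp_mitral_cortex"]], p[["psp_inter_cortex"]],
    p[["psp_cortex_motor"]]))))
  U <- c(p[["u_sensor_mitral"]], p[["u_mitral_inter"]],
         p[["u_mitral_cortex"]], p[["u_inter_cortex"]],
         p[["u_cortex_motor"]])
  r_rec <- c(p[["rec_sensor_mitral"]], p[["rec_mitral_inter"]],
             p[["rec_mitral_cortex"]], p[["rec_inter_cortex"]],
             p[["rec_cortex_motor"]])
  mode_i <- match(cfgS$branch_mode, c("thresholded", "linear", "sigmoidal")) - 1L

  net <- new.env(parent = emptyenv())
  net$config <- cfgS
  net$genome_values <- p
  net$seed <- seed
  net$cfg <- list(
    n_sensor = cfgS$n_sensors, n_mitral = n_mitral,
    n_inter = cfgS$n_inter, n_cortex = cfgS$n_cortex,
    branches = cfgS$branches, n_motor = cfgS$n_motor,
    exc_per_branch = cfgS$exc_per_branch,
    inh_per_branch = cfgS$inh_per_branch,
    inter_fanin = cfgS$inter_fanin, cluster_size = cfgS$cluster_size,
    branch_mode_i = mode_i,
    n_b = max(1L, min(cfgS$branches, as.integer(round(p[["n_b"]])))),
    branch_gain = p[["branch_gain"]],
    theta_int = p[["theta_int"]], theta_m = p[["theta_m"]],
    eta = HOMEO_ETA, tau_avg = HOMEO_TAU_AVG,
    theta_min = HOMEO_THETA_MIN, theta_max = HOMEO_THETA_MAX,
    branch_target = p[["branch_target"]], soma_target = p[["soma_target"]],
    homeo_on = homeostasis, align_inhibition = cfgS$align_inhibition,
    w = w, D = D, U = U, r_rec = r_rec
  )
  net$wiring <- wiring
  class(net) <- "network"
  reset_network(net)
  net
}

#' Reset a network's dynamic state
#'
#' Zeroes all layer activities and PSP buffers, restores depression
#' resources to 1 and thresholds to their genome initial values. Wiring is
#' untouched.
#'
#' @param net A [build_network()] network.
#' @return The network, invisibly.
#' @export
reset_network <- function(net) {
  stopifnot(inherits(net, "network"))
  cfg <- net$cfg
  p <- net$genome_values
  n_syn <- c(cfg$n_sensor, length(net$wiring$inter_src),
             length(net$wiring$cx_e_src), length(net$wiring$cx_i_src),
             length(net$wiring$mo_src))
  net$S <- numeric(cfg$n_sensor)
  net$M <- numeric(cfg$n_mitral)
  net$Md <- numeric(cfg$n_mitral)
  net$I <- numeric(cfg$n_inter)
  net$Cx <- numeric(cfg$n_cortex)
  net$Mo <- numeric(cfg$n_motor)
  net$R <- lapply(n_syn, function(n) rep(1, n))
  net$P <- lapply(n_syn, function(n) numeric(n))
  net$ring <- lapply(seq_len(5), function(k) numeric(n_syn[k] * cfg$D[k]))
  net$cur <- integer(5)
  net$theta_b <- rep(p[["theta_b0"]], cfg$n_cortex * cfg$branches)
  net$theta_s <- rep(p[["theta_s0"]], cfg$n_cortex)
  net$avg_b <- rep(cfg$branch_target, cfg$n_cortex * cfg$branches)
  net$avg_s <- rep(cfg$soma_target, cfg$n_cortex)
  net$drive_b <- numeric(cfg$n_cortex * cfg$branches)
  net$drive_s <- numeric(cfg$n_cortex)
  net$t <- 0L
  invisible(net)
}

#' @export
print.network <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(paste0(
    "<network> %d sensors -> %d mitral -> %d interneurons / %d cortical",
    " neurons (%d branches) -> %d motor units\n"),
    cfg$n_sensor, cfg$n_mitral, cfg$n_inter, cfg$n_cortex, cfg$branches,
    cfg$n_motor))
  cat(sprintf("  cortical afferent synapses: %d; timestep %d\n",
              length(x$wiring$cx_e_src) + length(x$wiring$cx_i_src), x$t))
  invisible(x)
}

#' Advance the network by one (or more) simulation timesteps
#'
#' Each timestep every stage reads only the previous timestep's output of
#' its presynaptic stage, so activity propagates sensor -> mitral ->
#' (interneuron, delayed mitral) -> cortex -> motor in five timesteps
#' inclusive. PSPs persist for their class duration, depression is applied
#' per activation, and homeostatic thresholds update when enabled.
#'
#' The network state advances in place (it is an environment).
#'
#' @param net A [build_network()] network.
#' @param sensor_activations Sensor activation vector in `[0, 1]`, length
#'   `n_sensors`, held constant over `n_substeps`.
#' @param n_substeps Timesteps to advance (e.g. 4 per beta cycle).
#' @param return_all Return the motor activity of every substep (matrix)
#'   instead of just the last.
#' @return Binary motor activity: length-`n_motor` vector (last substep), or
#'   an `n_substeps x n_motor` matrix when `return_all = TRUE`.
#' @export
step_network <- function(net, sensor_activations, n_substeps = 1L,
                         return_all = FALSE) {
  if (length(sensor_activations) != net$cfg$n_sensor)
    stop("sensor vector length does not match the array", call. = FALSE)
  if (!all(is.finite(sensor_activations)))
    stop("non-finite sensor activations", call. = FALSE)
  st <- list(cfg = net$cfg, wiring = net$wiring,
             R = net$R, P = net$P, ring = net$ring, cur = net$cur,
             S = net$S, M = net$M, Md = net$Md, I = net$I,
             Cx = net$Cx, Mo = net$Mo,
             theta_b = net$theta_b, theta_s = net$theta_s,
             avg_b = net$avg_b, avg_s = net$avg_s,
             drive_b = net$drive_b, drive_s = net$drive_s)
  out <- cpp_net_step(st, as.numeric(sensor_activations),
                      as.integer(n_substeps))
  net$t <- net$t + as.integer(n_substeps)
  if (return_all) out else out[nrow(out), ]
}

#' Enable or freeze homeostatic threshold adjustment
#'
#' @param net A network.
#' @param on `TRUE` to adapt thresholds, `FALSE` to freeze them
#'   (calibration-style operation).
#' @return The network, invisibly.
#' @export
set_homeostasis <- function(net, on) {
  stopifnot(inherits(net, "network"))
  cfg <- net$cfg
  cfg$homeo_on <- isTRUE(on)
  net$cfg <- cfg
  invisible(net)
}

#' Dendritic branch activation
#'
#' The three dendritic integration modes: `"thresholded"` returns 1 when the
#' weighted PSP sum reaches the branch threshold (ties activate), `"linear"`
#' passes the sum through unchanged, `"sigmoidal"` applies
#' `1 / (1 + exp(-gain * (sum - theta)))`.
#'
#' @param input Weighted PSP sum(s).
#' @param mode One of `"thresholded"`, `"linear"`, `"sigmoidal"`.
#' @param theta Branch threshold.
#' @param gain Sigmoid gain.
#' @return Branch output(s).
#' @export
branch_activation <- function(input, mode = c("thresholded", "linear",
                                              "sigmoidal"),
                              theta = 0.5, gain = 4) {
  mode <- match.arg(mode)
  switch(mode,
         thresholded = as.numeric(input >= theta),
         linear = input,
         sigmoidal = 1 / (1 + exp(-gain * (input - theta))))
}

#' First-order synaptic depression update
#'
#' On presynaptic activity `a` in `[0, 1]` the effective release is
#' `w * a * R`; the resource then depletes, `R <- R * (1 - U * a)`, and
#' recovers first-order every timestep, `R <- R + r_rec * (1 - R)`. Under
#' sustained every-step activation the resource converges to
#' `R* = r_rec / (r_rec + U - U * r_rec)`.
#'
#' @param resources Resource vector `R` in `[0, 1]`.
#' @param activity Presynaptic activity in `[0, 1]` (recycled).
#' @param U Depression fraction in `[0, 1]`.
#' @param r_rec Recovery rate per timestep.
#' @param w Synaptic weight.
#' @return List with `effective` (released weight, `w * a * R`) and
#'   `resources` (updated `R`, still in `[0, 1]`).
#' @export
apply_depression <- function(resources, activity, U, r_rec, w = 1) {
  stopifnot(all(resources >= 0), all(resources <= 1),
            all(activity >= 0), all(activity <= 1),
            U >= 0, U <= 1, r_rec >= 0, r_rec <= 1)
  release <- activity * resources
  resources <- resources - U * release
  resources <- resources + r_rec * (1 - resources)
  list(effective = w * release, resources = resources)
}

#' Local homeostatic excitability update
#'
#' Maintains a per-unit exponential moving average of activity and nudges
#' the threshold toward holding that average at the target rate: the
#' threshold rises when activity exceeds target and falls below it,
#' clipped to `[theta_min, theta_max]`.
#'
#' @param avg Activity averages in `[0, 1]`.
#' @param theta Thresholds.
#' @param activity Current activity (binary or graded, recycled).
#' @param target Target average rate in `(0, 1)`.
#' @param eta Adjustment rate (fixed package constant by default).
#' @param tau_avg Averaging time constant in timesteps.
#' @param theta_min,theta_max Threshold bounds.
#' @return List with updated `avg` and `theta`.
#' @export
update_homeostasis <- function(avg, theta, activity, target,
                               eta = HOMEO_ETA, tau_avg = HOMEO_TAU_AVG,
                               theta_min = HOMEO_THETA_MIN,
                               theta_max = HOMEO_THETA_MAX) {
  stopifnot(target > 0, target < 1)
  avg <- avg + (activity - avg) / tau_avg
  theta <- pmin(theta_max, pmax(theta_min, theta + eta * (avg - target)))
  list(avg = avg, theta = theta)
}

#' Calibrate branch (and soma) thresholds to the homeostatic targets
#'
#' A calibration period: the network is driven with a representative sensor
#' input (homeostasis frozen), the raw dendritic drives are recorded once
#' the PSP pipeline has filled, and the branch threshold — a global value
#' during calibration — is set to the drive quantile at which the average
#' branch activity equals the genome's branch target rate. In the linear
#' and sigmoidal dendrite modes the soma threshold is calibrated the same
#' way against the soma target. Local homeostasis then refines the
#' thresholds per branch and per neuron during operation.
#'
#' @param net A network (state is reset first).
#' @param input Representative sensor activation vector.
#' @param probe_steps Timesteps driven during calibration.
#' @param settle Timesteps discarded while the pipeline fills.
#' @return The network, invisibly.
#' @export
calibrate_network <- function(net, input, probe_steps = 56L,
                              settle = 32L) {
  stopifnot(inherits(net, "network"), probe_steps > settle)
  reset_network(net)
  homeo <- net$cfg$homeo_on
  set_homeostasis(net, FALSE)
  nb <- length(net$theta_b)
  drives_b <- numeric(0)
  drives_s <- numeric(0)
  for (t in seq_len(probe_steps)) {
    step_network(net, input)
    if (t > settle) {
      drives_b <- c(drives_b, net$drive_b)
      if (net$cfg$branch_mode_i != 0L)
        drives_s <- c(drives_s, net$drive_s)
    }
  }
  q <- unname(stats::quantile(drives_b, 1 - net$cfg$branch_target,
                              type = 7))
  q <- min(HOMEO_THETA_MAX, max(HOMEO_THETA_MIN, q))
  theta_b <- net$theta_b
  theta_b[] <- q
  if (net$cfg$branch_mode_i != 0L) {
    qs <- unname(stats::quantile(drives_s, 1 - net$cfg$soma_target,
                                 type = 7))
    theta_s <- net$theta_s
    theta_s[] <- min(HOMEO_THETA_MAX, max(HOMEO_THETA_MIN, qs))
  }
  reset_network(net)
  net$theta_b[] <- theta_b
  if (net$cfg$branch_mode_i != 0L) net$theta_s[] <- theta_s
  set_homeostasis(net, homeo)
  invisible(net)
}

#' Measure the sensor-to-motor propagation latency
#'
#' Feeds a constant step stimulus into a freshly reset network and returns
#' the inclusive count of timesteps from stimulus onset to the first
#' nonzero motor activity (five for the full pipeline).
#'
#' @param net A network (reset before measuring).
#' @param stimulus Sensor activation vector; default full drive.
#' @param max_steps Bound after which `NA` (no propagation) is returned.
#' @return Integer latency in timesteps, or `NA_integer_` if the stimulus
#'   never reaches the motor layer.
#' @export
measure_latency <- function(net, stimulus = NULL, max_steps = 50L) {
  stopifnot(inherits(net, "network"))
  if (is.null(stimulus)) stimulus <- rep(1, net$cfg$n_sensor)
  reset_network(net)
  for (t in seq_len(max_steps)) {
    mo <- step_network(net, stimulus)
    if (any(mo > 0)) return(as.integer(t))
  }
  NA_integer_
}

#' Structural counts of a built network
#'
#' @param net A network.
#' @return One-row tibble with the architecture counts (cortical neurons,
#'   branches, inputs per neuron, cortical synapses, mitral units, motor
#'   units and afferents).
#' @export
network_counts <- function(net) {
  cfg <- net$cfg
  tibble::tibble(
    n_sensors = cfg$n_sensor,
    n_mitral = cfg$n_mitral,
    n_inter = cfg$n_inter,
    n_cortex = cfg$n_cortex,
    branches = cfg$branches,
    inputs_per_neuron = cfg$branches * (cfg$exc_per_branch +
                                          cfg$inh_per_branch),
    cortex_synapses = length(net$wiring$cx_e_src) +
      length(net$wiring$cx_i_src),
    n_motor = cfg$n_motor,
    motor_afferents = length(net$wiring$mo_src) %/% cfg$n_motor
  )
}
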