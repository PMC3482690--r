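#' Size-principle motor pools
#'
#' The 16 motor units are divided into four pools — left-forward,
#' left-backward, right-forward, right-backward — with forces 1, 2, 4 and 8
#' assigned to the four units of each pool (the size principle: units of
#' graded power are recruited to grade total output). Negative tread
#' currents are encoded by the backward pool of each side. Default
#' assignment is by index blocks (units 1-4 LF, 5-8 LB, 9-12 RF, 13-16 RB)
#' with forces in index order.
#'
#' @param gain Output gain applied to the net pool sums (gain 1 keeps each
#'   tread current in `[-15, 15]`).
#' @param assignment Optional integer vector of length 16 mapping unit to
#'   pool (1 = LF, 2 = LB, 3 = RF, 4 = RB), 4 units per pool.
#' @param forces Forces within each pool, exactly `c(1, 2, 4, 8)` by
#'   default.
#' @return A `motor_pools` object.
#' @export
motor_pools <- function(gain = 1, assignment = rep(1:4, each = 4),
                        forces = c(1, 2, 4, 8)) {
  stopifnot(length(assignment) == 16, all(sort(unique(assignment)) == 1:4),
            all(table(assignment) == 4), length(forces) == 4)
  force_per_unit <- numeric(16)
  for (p in 1:4) force_per_unit[assignment == p] <- forces
  structure(list(gain = gain, assignment = as.integer(assignment),
                 forces = forces, force_per_unit = force_per_unit),
            class = "motor_pools")
}

#' Map motor-unit activity to signed tread currents
#'
#' The active forces of each side's forward pool are summed and the backward
#' pool's sum subtracted, giving a net signed current per tread, scaled by
#' the pool gain and clamped to the signed 8-bit range `[-127, 127]`.
#'
#' @param activity Binary vector of 16 motor-unit activities.
#' @param pools A [motor_pools()].
#' @return Integer vector `c(I_L, I_R)`.
#' @export
motor_units_to_currents <- function(activity, pools = motor_pools()) {
  if (length(activity) != 16 || any(activity != 0 & activity != 1))
    stop("activity must be 16 binary values", call. = FALSE)
  f <- pools$force_per_unit * activity
  i_l <- sum(f[pools$assignment == 1]) - sum(f[pools$assignment == 2])
  i_r <- sum(f[pools$assignment == 3]) - sum(f[pools$assignment == 4])
  out <- round(pools$gain * c(i_l, i_r))
  as.integer(pmax(-127, pmin(127, out)))
}

#' Parameters of the five-state exploratory behavior
#'
#' @param theta_low,theta_high Absolute summed-concentration thresholds
#'   separating the LOW and HIGH states.
#' @param epsilon Deadband on the concentration change over 1 s used by the
#'   RISING/FALLING states.
#' @param lookback Seconds between the current sample and the comparison
#'   sample (1 s).
#' @param cast_dwell_s Seconds per casting half-cycle in FALLING.
#' @param reverse_dwell_s Seconds spent reversing after a collision.
#' @param surge,slow,reverse Tread-current pairs for RISING, HIGH and
#'   REVERSING.
#' @param cast_mag Casting turn current magnitude.
#' @param low_base,low_turn Forward current and random turn amplitude of the
#'   LOW biased random walk.
#' @return A `behavior_params` list.
#' @export
behavior_params <- function(theta_low = 0.05, theta_high = 0.6,
                            epsilon = 0.02, lookback = 1,
                            cast_dwell_s = 0.3, reverse_dwell_s = 1,
                            surge = c(15L, 15L), slow = c(4L, 4L),
                            reverse = c(-10L, -10L), cast_mag = 12L,
                            low_base = 8L, low_turn = 4L) {
  stopifnot(theta_low < theta_high, epsilon >= 0, lookback > 0)
  structure(as.list(environment()), class = "behavior_params")
}

#' Classify the current sensory state of the exploratory behavior
#'
#' Five mutually exclusive states in priority order: REVERSING (zero
#' proximity, i.e. wall contact, or an active reversing timer), HIGH
#' (summed concentration at or above `theta_high`), RISING / FALLING
#' (change versus the sample `lookback` seconds earlier exceeds `epsilon`),
#' else LOW. With insufficient history the cold-start default is LOW.
#'
#' @param history Numeric vector of summed concentrations, one per CFD step,
#'   most recent last.
#' @param prox Current proximity to the nearest wall (m); 0 on contact.
#' @param params A [behavior_params()].
#' @param dt Seconds between history samples.
#' @param reversing_timer Steps of reversing dwell remaining (> 0 keeps the
#'   REVERSING state active after contact ends).
#' @return One of `"REVERSING"`, `"HIGH"`, `"RISING"`, `"FALLING"`, `"LOW"`.
#' @export
classify_state <- function(history, prox, params = behavior_params(),
                           dt = 0.030, reversing_timer = 0L) {
  if (prox <= 0 || reversing_timer > 0) return("REVERSING")
  n <- length(history)
  lag <- round(params$lookback / dt)
  c_now <- if (n >= 1) history[n] else 0
  if (c_now >= params$theta_high) return("HIGH")
  if (n > lag) {
    c_then <- history[n - lag]
    if (c_now - c_then > params$epsilon) return("RISING")
    if (c_then - c_now > params$epsilon) return("FALLING")
  }
  "LOW"
}

#' Motor command for a behavior state
#'
#' RISING surges straight ahead at full current; HIGH creeps forward;
#' FALLING casts (alternating opposite turns every `cast_dwell_s`);
#' LOW performs a biased random walk (forward plus a seeded random turn
#' drawn from the current RNG stream); REVERSING backs up. Deterministic
#' given the RNG state and `tick`.
#'
#' @param state A state name from [classify_state()].
#' @param tick Steps already spent in this state (drives the casting
#'   alternation).
#' @param params A [behavior_params()].
#' @param dt Seconds per step.
#' @return Integer `c(I_L, I_R)`.
#' @export
state_to_command <- function(state, tick = 0L, params = behavior_params(),
                             dt = 0.030) {
  switch(state,
    RISING = params$surge,
    HIGH = params$slow,
    FALLING = {
      half <- max(1L, round(params$cast_dwell_s / dt))
      if ((tick %/% half) %% 2 == 0)
        c(params$cast_mag, -params$cast_mag)
      else c(-params$cast_mag, params$cast_mag)
    },
    LOW = {
      turn <- sample.int(2L * params$low_turn + 1L, 1L) - params$low_turn - 1L
      as.integer(c(params$low_base + turn, params$low_base - turn))
    },
    REVERSING = params$reverse,
    stop("unknown behavior state: ", state, call. = FALSE)
  )
}

#' Built-in five-state exploratory behavior controller
#'
#' A drop-in controller for [run_trial()]: tracks the summed-concentration
#' history, classifies the sensory state each CFD step and issues the
#' corresponding tread currents. Uses the trial RNG stream for the LOW
#' random walk, so trials are reproducible under the trial seed.
#'
#' @param params A [behavior_params()].
#' @param dt Seconds per CFD step (must match the scenario grid).
#' @return A controller object (see [run_trial()] for the interface).
#' @export
behavior_controller <- function(params = behavior_params(), dt = 0.030) {
  env <- new.env(parent = emptyenv())
  env$params <- params
  env$dt <- dt
  reset <- function() {
    env$history <- numeric(0)
    env$state <- "LOW"
    env$tick <- 0L
    env$rev_timer <- 0L
  }
  step <- function(concentrations, prox, n_substeps = 4L) {
    env$history <- c(env$history, sum(concentrations))
    st <- classify_state(env$history, prox, env$params, env$dt,
                         env$rev_timer)
    if (st == "REVERSING") {
      if (env$state != "REVERSING")
        env$rev_timer <- max(1L, round(env$params$reverse_dwell_s / env$dt))
      env$rev_timer <- env$rev_timer - 1L
    }
    env$tick <- if (st == env$state) env$tick + 1L else 0L
    env$state <- st
    state_to_command(st, env$tick, env$params, env$dt)
  }
  reset()
  structure(list(reset = reset, step = step, kind = "behavior"),
            class = "pb_controller")
}

#' Null controller (always zero currents)
#'
#' @return A controller issuing `c(0, 0)` every step.
#' @export
zero_controller <- function() {
  structure(list(reset = function() invisible(NULL),
                 step = function(concentrations, prox, n_substeps = 4L)
                   c(0L, 0L),
                 kind = "zero"),
            class = "pb_controller")
}

#' Neural controller: sensor chemistry + circuit + motor pools
#'
#' Wraps a built network as a trial controller: per CFD step the sampled
#' odorant concentrations are converted to motif concentrations (plus a
#' background draw if configured), transduced by the sensor array
#' (instantaneous steady state by default, or first-order kinetics), the
#' network advances `n_substeps` timesteps, and the final motor activity is
#' mapped to tread currents through the size-principle pools.
#'
#' @param net A [build_network()] network.
#' @param array A [generate_sensor_array()] matching `net`'s sensor count.
#' @param odorants List of [odorant()] objects, one per dye channel in use.
#' @param pools A [motor_pools()]; its gain defaults to the genome's
#'   `motor_gain`.
#' @param bg Optional [background()].
#' @param kinetic Use the finite-rate sensor kinetics (Euler updates at the
#'   neural timestep) instead of instantaneous activation.
#' @param dt_neural Seconds per neural timestep (for the kinetic mode).
#' @param calibrate Run a [calibrate_network()] calibration period on the
#'   first sensory sample of each trial (recommended: random genomes start
#'   with arbitrary branch thresholds).
#' @return A controller object for [run_trial()].
#' @export
neural_controller <- function(net, array, odorants, pools = NULL,
                              bg = NULL, kinetic = FALSE,
                              dt_neural = 0.0075, calibrate = TRUE) {
  stopifnot(inherits(net, "network"),
            array$n_sensors == net$cfg$n_sensor)
  if (is.null(pools))
    pools <- motor_pools(gain = net$genome_values[["motor_gain"]])
  env <- new.env(parent = emptyenv())
  env$A <- numeric(array$n_sensors)
  env$calibrated <- FALSE
  rf <- net$genome_values[["sensor_rf"]]
  rb <- net$genome_values[["sensor_rbeta"]]
  reset <- function() {
    reset_network(net)
    env$A <- numeric(array$n_sensors)
    env$calibrated <- FALSE
  }
  step <- function(concentrations, prox, n_substeps = 4L) {
    m <- motif_concentrations(concentrations, odorants,
                              sample_background(bg))
    target <- array_activations(array, m)
    if (calibrate && !env$calibrated) {
      # calibration period on the first sensory sample of the trial
      calibrate_network(net, target)
      env$calibrated <- TRUE
    }
    act <- if (kinetic) {
      env$A <- kinetic_update(env$A, target, rf, rb,
                              dt_neural * n_substeps)
      env$A
    } else target
    mo <- step_network(net, act, n_substeps)
    motor_units_to_currents(mo, pools)
  }
  structure(list(reset = reset, step = step, kind = "neural",
                 net = net, pools = pools),
            class = "pb_controller")
}
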