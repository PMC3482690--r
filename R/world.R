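#' Robot agent state
#'
#' A rectangular differential-drive robot (default footprint 0.12 m x
#' 0.10 m, mirroring a small tracked robot) with pose, linear/angular
#' speeds, and the last commanded tread currents. The odor sensor sits at
#' the front-center of the chassis by default.
#'
#' @param position Length-2 position of the body center (m).
#' @param heading Heading (rad; 0 = +x).
#' @param speed,ang_speed Linear (m/s) and angular (rad/s) speed.
#' @param length,width Footprint dimensions (m); `length` is along the
#'   heading.
#' @param sensor_offset Sensor location along the heading axis relative to
#'   the body center (m); default front-center (`length / 2`).
#' @return A `robot_state` object.
#' @export
robot_state <- function(position = c(0, 0), heading = 0, speed = 0,
                        ang_speed = 0, length = 0.12, width = 0.10,
                        sensor_offset = NULL) {
  if (is.null(sensor_offset)) sensor_offset <- length / 2
  structure(list(position = as.numeric(position), heading = heading,
                 speed = speed, ang_speed = ang_speed,
                 length = length, width = width,
                 sensor_offset = sensor_offset, I_L = 0L, I_R = 0L),
            class = "robot_state")
}

#' Sensor position of a robot
#'
#' @param robot A [robot_state()].
#' @return Length-2 world position (m) of the odor sensor.
#' @export
sensor_position <- function(robot) {
  robot$position + robot$sensor_offset *
    c(cos(robot$heading), sin(robot$heading))
}

#' Corner coordinates of the robot footprint
#'
#' @param robot A [robot_state()].
#' @return 4 x 2 matrix of corner positions (m), counter-clockwise.
#' @export
robot_corners <- function(robot) {
  d <- c(cos(robot$heading), sin(robot$heading))
  p <- c(-d[2], d[1])
  hl <- robot$length / 2; hw <- robot$width / 2
  rbind(robot$position + hl * d + hw * p,
        robot$position - hl * d + hw * p,
        robot$position - hl * d - hw * p,
        robot$position + hl * d - hw * p)
}

#' Advance the robot one time step
#'
#' Differential-drive kinematics with velocity-proportional friction: the
#' tread currents set target speeds `v* = k_m (I_L + I_R) / 2` and
#' `w* = k_m (I_R - I_L) / W`; speeds move toward their targets (instantly
#' when `tau_motor = 0`, the default kinematic model) and then decay by the
#' friction factor `(1 - mu * dt)`; the pose is integrated with forward
#' Euler (position advanced along the pre-update heading).
#'
#' @param robot A [robot_state()].
#' @param I_L,I_R Signed tread currents in `[-127, 127]`.
#' @param dt Time step (s), `> 0`.
#' @param mu Friction rate (1/s).
#' @param k_m Current-to-speed constant (m/s per current unit).
#' @param W Track separation (m).
#' @param tau_motor Motor time constant (s); 0 = instant target attainment.
#' @return The advanced `robot_state`.
#' @export
step_robot <- function(robot, I_L, I_R, dt, mu = 0.5, k_m = 0.004,
                       W = 0.10, tau_motor = 0) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (abs(I_L) > 127 || abs(I_R) > 127)
    stop("tread currents outside signed 8-bit range", call. = FALSE)
  v_t <- k_m * (I_L + I_R) / 2
  w_t <- k_m * (I_R - I_L) / W
  alpha <- if (tau_motor <= 0) 1 else min(1, dt / tau_motor)
  v <- robot$speed + alpha * (v_t - robot$speed)
  w <- robot$ang_speed + alpha * (w_t - robot$ang_speed)
  decay <- max(0, 1 - mu * dt)
  v <- v * decay
  w <- w * decay
  robot$position <- robot$position +
    v * c(cos(robot$heading), sin(robot$heading)) * dt
  robot$heading <- robot$heading + w * dt
  robot$speed <- v
  robot$ang_speed <- w
  robot$I_L <- as.integer(round(I_L)); robot$I_R <- as.integer(round(I_R))
  robot
}

# minimum distance between segment p1-p2 and segment q1-q2
seg_seg_dist <- function(p1, p2, q1, q2) {
  seg_pt <- function(a, b, p) {
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab * ab), 1e-12)
    t <- min(1, max(0, t))
    sqrt(sum((a + t * ab - p)^2))
  }
  orient <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  # proper intersection -> distance 0
  if (orient(p1, p2, q1) * orient(p1, p2, q2) < 0 &&
      orient(q1, q2, p1) * orient(q1, q2, p2) < 0) return(0)
  min(seg_pt(p1, p2, q1), seg_pt(p1, p2, q2),
      seg_pt(q1, q2, p1), seg_pt(q1, q2, p2))
}

#' Proximity of the robot to the nearest wall or obstacle
#'
#' Minimum Euclidean distance from the robot footprint to the inner face of
#' the outer walls and to any internal boundary; 0 on contact or
#' penetration (the trigger of the behavioral reversing mode).
#'
#' @param robot A [robot_state()].
#' @param walls A wall set from [scenario_walls()] (outer bounds plus
#'   obstacle rectangles in metres).
#' @return Distance in metres, `>= 0`.
#' @export
proximity <- function(robot, walls) {
  corners <- robot_corners(robot)
  b <- walls$bounds   # c(x0, y0, x1, y1), inner faces of the outer wall
  d_out <- min(corners[, 1] - b[1], b[3] - corners[, 1],
               corners[, 2] - b[2], b[4] - corners[, 2])
  d <- max(0, d_out)
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
  for (ob in walls$obstacles) {
    oc <- rbind(c(ob[1], ob[2]), c(ob[3], ob[2]),
                c(ob[3], ob[4]), c(ob[1], ob[4]))
    inside_ob <- all(robot$position >= ob[c(1, 2)] &
                       robot$position <= ob[c(3, 4)])
    if (inside_ob) return(0)
    dmin <- Inf
    for (e1 in seq_len(4)) {
      for (e2 in seq_len(4)) {
        dmin <- min(dmin, seg_seg_dist(
          corners[edges[e1, 1], ], corners[edges[e1, 2], ],
          oc[edges[e2, 1], ], oc[edges[e2, 2], ]))
      }
    }
    # corner containment (overlap without proper edge crossing)
    if (any(corners[, 1] >= ob[1] & corners[, 1] <= ob[3] &
              corners[, 2] >= ob[2] & corners[, 2] <= ob[4])) dmin <- 0
    d <- min(d, dmin)
  }
  d
}

#' Define a trial scenario
#'
#' A scenario bundles the world definition for one closed-loop trial: the
#' flow-grid configuration, odor and wind sources, internal boundaries, the
#' odorants carried by each dye channel, the robot start pose and body
#' parameters, the target source with its proximity radius, the trial
#' duration, and the neural/CFD coupling cadence (4 neural timesteps per
#' 30 ms CFD step, i.e. one beta cycle per CFD update).
#'
#' @param grid Named list of [flow_grid()] arguments (without `obstacles`).
#' @param sources List of [plume_source()] objects.
#' @param winds List of [wind_source()] objects.
#' @param obstacles List of [obstacle()] objects.
#' @param odorants List of [odorant()] objects (channel-linked).
#' @param bg Optional [background()].
#' @param robot_start Named list `x`, `y`, `heading`.
#' @param robot Named list of robot parameters (`length`, `width`, `k_m`,
#'   `W`, `mu`, `tau_motor`, `effect_magnitude`).
#' @param target_source Index into `sources` of the target plume.
#' @param proximity_radius Trial success radius around the target source
#'   (m), `> 0`.
#' @param max_duration Trial cap `T_max` (s), `> 0`.
#' @param warmup_steps CFD steps run before the robot is released, letting
#'   the plume develop.
#' @param neural_steps_per_cfd_step Neural timesteps per CFD step.
#' @param seed Scenario seed (wiring / fixture determinism).
#' @param behavior A [behavior_params()] for the built-in controller.
#' @param name Label.
#' @return A `scenario` object.
#' @export
scenario <- function(grid = list(), sources, winds = list(),
                     obstacles = list(), odorants, bg = NULL,
                     robot_start = list(x = 1, y = 1, heading = 0),
                     robot = list(), target_source = 1,
                     proximity_radius = 0.15, max_duration = 30,
                     warmup_steps = 0, neural_steps_per_cfd_step = 4,
                     seed = 1, behavior = behavior_params(),
                     name = "scenario") {
  stopifnot(length(sources) >= 1,
            target_source >= 1, target_source <= length(sources),
            proximity_radius > 0, max_duration > 0)
  robot_defaults <- list(length = 0.12, width = 0.10, k_m = 0.004,
                         W = 0.10, mu = 0.5, tau_motor = 0,
                         effect_magnitude = 1)
  robot <- utils::modifyList(robot_defaults, robot)
  structure(list(grid = grid, sources = sources, winds = winds,
                 obstacles = obstacles, odorants = odorants, bg = bg,
                 robot_start = robot_start, robot = robot,
                 target_source = as.integer(target_source),
                 proximity_radius = proximity_radius,
                 max_duration = max_duration,
                 warmup_steps = as.integer(warmup_steps),
                 neural_steps_per_cfd_step =
                   as.integer(neural_steps_per_cfd_step),
                 seed = as.integer(seed), behavior = behavior,
                 name = name),
            class = "scenario")
}

#' Build the flow grid of a scenario
#'
#' @param scn A [scenario()].
#' @return A fresh [flow_grid()] with the scenario's obstacles.
#' @export
scenario_grid <- function(scn) {
  do.call(flow_grid, c(scn$grid, list(obstacles = scn$obstacles)))
}

#' Wall set of a scenario (for proximity computation)
#'
#' @param scn A [scenario()].
#' @return List with `bounds` (inner faces of the outer wall, m) and
#'   `obstacles` (world rectangles, m).
#' @export
scenario_walls <- function(scn) {
  g <- scenario_grid(scn)
  h <- g$cell_size
  obs <- lapply(scn$obstacles, function(ob)
    c((ob$x0 - 1) * h, (ob$y0 - 1) * h, ob$x1 * h, ob$y1 * h))
  list(bounds = c(h, h, (g$nx - 1) * h, (g$ny - 1) * h), obstacles = obs)
}

#' World position of a scenario source
#'
#' @param scn A [scenario()].
#' @param k Source index (default: the target source).
#' @return Length-2 position (m) of the source cell center.
#' @export
source_position <- function(scn, k = scn$target_source) {
  h <- scn$grid$cell_size %||% 0.02
  (scn$sources[[k]]$cell - 0.5) * h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Warm up a scenario's plume field
#'
#' Runs the scenario's CFD (winds + sources, no robot) for its configured
#' warm-up steps, returning the developed grid. [run_trial()] accepts the
#' result as `initial_grid` so repeated trials of the same scenario can
#' share one warm-up.
#'
#' @param scn A [scenario()].
#' @param steps Override of `scn$warmup_steps`.
#' @return A [flow_grid()].
#' @export
warmup_grid <- function(scn, steps = NULL) {
  g <- scenario_grid(scn)
  n <- steps %||% scn$warmup_steps
  for (k in seq_len(n)) g <- step_fluid(g, scn$winds, scn$sources)
  g
}

#' Encode a sensor message / decode a motor message (ASCII line protocol)
#'
#' The world and brain exchange a few tens of bytes per timestep over an
#' ASCII line protocol: `"SENSE c1 c2 c3\n"` with fixed 6-decimal floats
#' (at most 40 bytes for three channels) and `"MOTOR l r\n"` with signed
#' integer tread currents. Round-trips are lossless at the stated
#' precision.
#'
#' @param concentrations Finite per-channel concentrations.
#' @return `encode_sense_message()`: a single string ending in newline.
#' @export
encode_sense_message <- function(concentrations) {
  stopifnot(all(is.finite(concentrations)))
  paste0("SENSE ", paste(sprintf("%.6f", concentrations), collapse = " "),
         "\n")
}

#' @rdname encode_sense_message
#' @param line A `"SENSE ..."` line.
#' @return `decode_sense_message()`: numeric concentration vector.
#' @export
decode_sense_message <- function(line) {
  parts <- strsplit(trimws(line), " +")[[1]]
  if (length(parts) < 2 || parts[1] != "SENSE")
    stop("protocol error: malformed SENSE line: ", line, call. = FALSE)
  out <- suppressWarnings(as.numeric(parts[-1]))
  if (any(is.na(out)))
    stop("protocol error: non-numeric SENSE payload: ", line, call. = FALSE)
  out
}

#' @rdname encode_sense_message
#' @param I_L,I_R Signed tread currents; values outside `[-127, 127]` are
#'   clamped with a warning.
#' @return `encode_motor_message()`: a single string ending in newline.
#' @export
encode_motor_message <- function(I_L, I_R) {
  if (abs(I_L) > 127 || abs(I_R) > 127) {
    warning("tread current out of 8-bit range; clamping")
    I_L <- max(-127, min(127, I_L)); I_R <- max(-127, min(127, I_R))
  }
  sprintf("MOTOR %d %d\n", as.integer(round(I_L)), as.integer(round(I_R)))
}

#' @rdname encode_sense_message
#' @return `decode_motor_message()`: integer vector `c(I_L, I_R)`.
#' @export
decode_motor_message <- function(line) {
  parts <- strsplit(trimws(line), " +")[[1]]
  if (length(parts) != 3 || parts[1] != "MOTOR")
    stop("protocol error: malformed MOTOR line: ", line, call. = FALSE)
  out <- suppressWarnings(as.integer(parts[-1]))
  if (any(is.na(out)))
    stop("protocol error: non-integer MOTOR payload: ", line, call. = FALSE)
  if (any(abs(out) > 127)) {
    warning("tread current out of 8-bit range; clamping")
    out <- pmax(-127L, pmin(127L, out))
  }
  out
}

#' Beta-cycle accounting of the neural/CFD scheduler
#'
#' Each CFD update stands for one beta oscillation cycle and advances the
#' neural system by `steps_per_cycle` timesteps, so 10,000 neural timesteps
#' correspond to 2,500 beta cycles at the default ratio of 4.
#'
#' @param n_neural_steps Number of neural timesteps.
#' @param steps_per_cycle Neural timesteps per beta cycle.
#' @return Number of beta cycles.
#' @export
beta_cycles <- function(n_neural_steps, steps_per_cycle = 4) {
  n_neural_steps / steps_per_cycle
}

# clamp the robot pose inside the outer walls; returns list(robot, hit)
clamp_to_bounds <- function(robot, walls) {
  b <- walls$bounds
  ct <- abs(cos(robot$heading)); st <- abs(sin(robot$heading))
  ex <- ct * robot$length / 2 + st * robot$width / 2
  ey <- st * robot$length / 2 + ct * robot$width / 2
  x <- min(max(robot$position[1], b[1] + ex), b[3] - ex)
  y <- min(max(robot$position[2], b[2] + ey), b[4] - ey)
  hit <- (x != robot$position[1]) || (y != robot$position[2])
  robot$position <- c(x, y)
  if (hit) robot$speed <- 0
  list(robot = robot, hit = hit)
}

#' Run one closed-loop trial
#'
#' Executes the sensorimotor loop: per CFD step the odorant concentrations
#' at the sensor are sampled, passed through the ASCII protocol round-trip
#' (so in-process and socket couplings see bit-identical inputs), fed to
#' the controller which advances `neural_steps_per_cfd_step` timesteps and
#' returns tread currents; the robot advances, its leading edge injects
#' equal-and-opposite forces into the flow, and the fluid steps. The trial
#' terminates at the first step with the robot within the proximity radius
#' of the target source, or at `T_max`.
#'
#' Fully reproducible: identical scenario, controller and seed give
#' bit-identical results.
#'
#' @param scn A [scenario()].
#' @param controller A controller (e.g. [neural_controller()],
#'   [behavior_controller()], [zero_controller()] or [socket_controller()]).
#' @param seed Trial seed (drives the controller RNG and background noise).
#' @param initial_grid Optional pre-warmed [flow_grid()] from
#'   [warmup_grid()]; when `NULL` the warm-up is run here.
#' @param log Keep per-step trajectory and concentration logs.
#' @return A `trial_result` with fields `reached`, `time_to_source` (capped
#'   at `T_max`), `final_distance`, `collisions`, `n_cfd_steps`,
#'   `n_neural_steps`, and (when `log = TRUE`) `trajectory` and
#'   `concentrations` tibbles with one row per CFD step.
#' @export
run_trial <- function(scn, controller, seed = 1, initial_grid = NULL,
                      log = TRUE) {
  stopifnot(inherits(scn, "scenario"), inherits(controller, "pb_controller"))
  grid <- if (is.null(initial_grid)) warmup_grid(scn) else initial_grid
  dt <- grid$dt
  n_steps <- ceiling(scn$max_duration / dt)
  walls <- scenario_walls(scn)
  target <- source_position(scn)
  robot <- robot_state(position = c(scn$robot_start$x, scn$robot_start$y),
                       heading = scn$robot_start$heading,
                       length = scn$robot$length, width = scn$robot$width)
  nsub <- scn$neural_steps_per_cfd_step
  K <- grid$n_channels
  src_cells <- lapply(scn$sources, function(s) s$cell)

  if (log) {
    traj <- matrix(NA_real_, n_steps, 7)
    conc_log <- matrix(NA_real_, n_steps, K)
    srcmax_log <- matrix(NA_real_, n_steps, K)
  }

  reached <- FALSE
  t_reach <- scn$max_duration
  collisions <- 0L
  steps_done <- 0L
  src_max <- numeric(K)

  src_chan <- vapply(scn$sources, function(s) s$channel, integer(1))
  h <- grid$cell_size
  nxg <- grid$nx; nyg <- grid$ny
  tryCatch(with_seed(seed, {
    controller$reset()
    for (s in seq_len(n_steps)) {
      dist <- sqrt(sum((robot$position - target)^2))
      if (dist <= scn$proximity_radius) {
        reached <- TRUE
        t_reach <- (s - 1) * dt
        break
      }
      sp <- sensor_position(robot)
      conc_raw <- numeric(K)
      for (k in seq_len(K))
        conc_raw[k] <- cpp_bilinear_sample(grid$dye[[k]], nxg, nyg,
                                           sp[1] / h, sp[2] / h)
      conc <- decode_sense_message(encode_sense_message(conc_raw))
      prox <- proximity(robot, walls)
      cmd <- controller$step(conc, prox, nsub)
      cmd <- pmax(-127L, pmin(127L, as.integer(round(cmd))))
      robot <- step_robot(robot, cmd[1], cmd[2], dt, mu = scn$robot$mu,
                          k_m = scn$robot$k_m, W = scn$robot$W,
                          tau_motor = scn$robot$tau_motor)
      cl <- clamp_to_bounds(robot, walls)
      robot <- cl$robot
      if (cl$hit) collisions <- collisions + 1L
      forces <- perturbation_forces_fast(grid, robot,
                                         scn$robot$effect_magnitude)
      grid <- step_fluid(grid, scn$winds, scn$sources, forces)
      for (sc in seq_along(src_cells)) {
        k <- src_chan[sc]
        dk <- grid$dye[[k]][src_cells[[sc]][1], src_cells[[sc]][2]]
        if (dk > src_max[k]) src_max[k] <- dk
      }
      steps_done <- s
      if (log) {
        traj[s, ] <- c((s - 1) * dt, robot$position, robot$heading,
                       cmd[1], cmd[2], prox)
        conc_log[s, ] <- conc
        srcmax_log[s, ] <- src_max
      }
    }
  }), error = function(e)
    stop("trial aborted (controller or numerical failure): ",
         conditionMessage(e), call. = FALSE))

  final_distance <- sqrt(sum((robot$position - target)^2))
  out <- list(
    reached = reached,
    time_to_source = if (reached) t_reach else scn$max_duration,
    final_distance = final_distance,
    collisions = collisions,
    n_cfd_steps = steps_done,
    n_neural_steps = steps_done * nsub,
    dt = dt,
    source_max = src_max,
    scenario_name = scn$name
  )
  if (log) {
    keep <- seq_len(steps_done)
    out$trajectory <- tibble::tibble(
      t = traj[keep, 1], x = traj[keep, 2], y = traj[keep, 3],
      heading = traj[keep, 4],
      I_L = as.integer(traj[keep, 5]), I_R = as.integer(traj[keep, 6]),
      proximity = traj[keep, 7])
    cc <- tibble::as_tibble(as.data.frame(conc_log[keep, , drop = FALSE]))
    names(cc) <- paste0("c", seq_len(K))
    out$concentrations <- dplyr::bind_cols(
      tibble::tibble(t = traj[keep, 1]), cc)
    sm <- srcmax_log[keep, , drop = FALSE]
    out$source_max_log <- sm
  }
  structure(out, class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf(
    "<trial_result> %s: %s, time %.2f s, final distance %.3f m, %d collision(s)\n",
    x$scenario_name, if (x$reached) "reached source" else "not reached",
    x$time_to_source, x$final_distance, x$collisions))
  invisible(x)
}
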