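test_that("differential-drive kinematics follow the target/friction model", {
  # zero currents: pure friction decay
  rb <- robot_state(c(1, 1), heading = 0, speed = 0.1)
  rb2 <- step_robot(rb, 0, 0, dt = 0.03, mu = 0.5, tau_motor = 0.2)
  expect_lte(rb2$speed, 0.1 * (1 - 0.5 * 0.03) + 1e-12)
  # equal currents: no rotation, straight drive
  rb <- robot_state(c(1, 1), heading = 0.7)
  for (k in 1:10) rb <- step_robot(rb, 20, 20, dt = 0.03)
  expect_equal(rb$heading, 0.7)
  expect_equal(rb$speed, 0.004 * 20 * (1 - 0.5 * 0.03))
  # opposite currents: pure rotation in place, closed-form rate
  rb <- robot_state(c(1, 1), heading = 0)
  for (k in 1:10) rb <- step_robot(rb, -15, 15, dt = 0.03)
  w_expected <- 0.004 * 30 / 0.10 * (1 - 0.5 * 0.03)
  expect_equal(rb$ang_speed, w_expected)
  expect_equal(rb$position, c(1, 1))
  expect_equal(rb$heading, 10 * w_expected * 0.03, tolerance = 1e-9)
  expect_error(step_robot(rb, 5, 5, dt = 0), "positive")
  expect_error(step_robot(rb, 200, 0, dt = 0.03), "8-bit")
})

test_that("proximity measures footprint distance to walls and obstacles", {
  # centered in an empty 2 m box: (1 - 0.06) = 0.94 m to the nearest wall
  walls <- list(bounds = c(0, 0, 2, 2), obstacles = list())
  rb <- robot_state(c(1, 1), heading = 0, length = 0.12, width = 0.10)
  expect_equal(proximity(rb, walls), 0.94)
  # flush against a wall -> 0
  rb_flush <- robot_state(c(0.06, 1), heading = 0)
  expect_equal(proximity(rb_flush, walls), 0)
  # penetration -> 0
  rb_pen <- robot_state(c(0.01, 1), heading = 0)
  expect_equal(proximity(rb_pen, walls), 0)
})

test_that("proximity agrees with a dense boundary-sampling oracle", {
  walls <- list(bounds = c(0, 0, 2, 2),
                obstacles = list(c(0.8, 0.8, 1.2, 1.2)))
  oracle <- function(rb) {
    corners <- robot_corners(rb)
    # dense points along the footprint boundary
    pts <- do.call(rbind, lapply(1:4, function(e) {
      a <- corners[e, ]; b <- corners[e %% 4 + 1, ]
      tt <- seq(0, 1, length.out = 60)
      cbind(a[1] + (b[1] - a[1]) * tt, a[2] + (b[2] - a[2]) * tt)
    }))
    d_out <- min(pts[, 1] - 0, 2 - pts[, 1], pts[, 2] - 0, 2 - pts[, 2])
    ob <- walls$obstacles[[1]]
    dx <- pmax(pmax(ob[1] - pts[, 1], pts[, 1] - ob[3]), 0)
    dy <- pmax(pmax(ob[2] - pts[, 2], pts[, 2] - ob[4]), 0)
    inside <- dx == 0 & dy == 0
    d_ob <- if (any(inside)) 0 else min(sqrt(dx^2 + dy^2))
    max(0, min(d_out, d_ob))
  }
  set.seed(12)
  for (k in 1:40) {
    rb <- robot_state(c(runif(1, 0.15, 1.85), runif(1, 0.15, 1.85)),
                      heading = runif(1, 0, 2 * pi))
    expect_equal(proximity(rb, walls), oracle(rb), tolerance = 2e-3)
  }
})

test_that("ASCII protocol round-trips at stated precision and stays under 40 bytes", {
  msg <- encode_sense_message(c(0, 0, 0))
  expect_identical(msg, "SENSE 0.000000 0.000000 0.000000\n")
  expect_identical(decode_sense_message(msg), c(0, 0, 0))
  expect_identical(decode_motor_message("MOTOR -15 15\n"), c(-15L, 15L))
  set.seed(6)
  for (k in 1:1000) {
    x <- runif(3, 0, 9.99)
    rt <- decode_sense_message(encode_sense_message(x))
    expect_true(all(abs(rt - x) <= 5e-7))
    expect_lte(nchar(encode_sense_message(x)), 40)
  }
  expect_lte(nchar(encode_motor_message(-127, 127)), 40)
  expect_error(decode_sense_message("SENSOR 1 2\n"), "protocol")
  expect_error(decode_motor_message("MOTOR 1\n"), "protocol")
  expect_warning(out <- decode_motor_message("MOTOR 300 0\n"), "clamp")
  expect_identical(out, c(127L, 0L))
})

test_that("scheduler arithmetic: four neural timesteps per beta cycle", {
  expect_equal(beta_cycles(10000), 2500)
  expect_equal(beta_cycles(8, steps_per_cycle = 4), 2)
  res <- run_trial(mini_scenario(max_duration = 0.3), zero_controller(),
                   seed = 1)
  expect_equal(res$n_neural_steps, res$n_cfd_steps * 4)
})

test_that("null controller never reaches; degenerate start reaches at t = 0", {
  scn <- mini_scenario(max_duration = 1.5)
  res <- run_trial(scn, zero_controller(), seed = 1)
  expect_false(res$reached)
  expect_equal(res$time_to_source, scn$max_duration)
  expect_equal(nrow(res$trajectory), res$n_cfd_steps)
  # started inside the proximity radius
  scn0 <- mini_scenario(robot_x = 0.79, robot_y = 0.5,
                        proximity_radius = 0.1)
  res0 <- run_trial(scn0, zero_controller(), seed = 1)
  expect_true(res0$reached)
  expect_equal(res0$time_to_source, 0)
  expect_equal(res0$n_cfd_steps, 0)
})

test_that("a straight-drive controller reaches on the kinematic schedule", {
  scn <- generate_fixture("corridor", seed = 1, scale = "desk")
  res <- run_trial(scn, scripted_controller(15L, 15L), seed = 1)
  expect_true(res$reached)
  # closed form: constant speed k_m * 15 * (1 - mu dt), check before move
  v <- 0.004 * 15 * (1 - 0.5 * 0.03)
  d0 <- sqrt(sum((c(scn$robot_start$x, scn$robot_start$y) -
                    source_position(scn))^2))
  n_pred <- ceiling((d0 - scn$proximity_radius) / (v * 0.03))
  expect_lte(abs(res$time_to_source / 0.03 - n_pred), 1)
})

test_that("trials are bit-reproducible for identical scenario, controller and seed", {
  scn <- mini_scenario(max_duration = 1.2)
  r1 <- run_trial(scn, behavior_controller(scn$behavior, dt = 0.03),
                  seed = 42)
  r2 <- run_trial(scn, behavior_controller(scn$behavior, dt = 0.03),
                  seed = 42)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$concentrations, r2$concentrations)
})

test_that("the robot cannot leave the outer boundary and collisions register", {
  scn <- mini_scenario(max_duration = 4.5, robot_x = 0.25, robot_y = 0.5,
                       heading = pi)   # drives straight into the west wall
  res <- run_trial(scn, scripted_controller(15L, 15L), seed = 1)
  walls <- scenario_walls(scn)
  expect_true(all(res$trajectory$x >= walls$bounds[1]))
  expect_true(all(res$trajectory$y >= walls$bounds[2]))
  expect_gt(res$collisions, 0)
  expect_true(any(res$trajectory$proximity == 0))
})

test_that("trial results tidy, glance and autoplot", {
  scn <- mini_scenario(max_duration = 0.6)
  res <- run_trial(scn, zero_controller(), seed = 1)
  expect_s3_class(tidy(res), "tbl_df")
  expect_named(tidy(res), c("t", "x", "y", "heading", "I_L", "I_R",
                            "proximity"))
  g <- glance(res)
  expect_equal(nrow(g), 1)
  expect_false(g$reached)
  p1 <- autoplot(res)
  p2 <- autoplot(res, "concentrations")
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})
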