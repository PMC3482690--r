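# independent finite-difference divergence oracle (net face outflow / h)
oracle_divergence <- function(grid) {
  nx <- grid$nx; ny <- grid$ny
  d <- matrix(NA_real_, nx, ny)
  for (i in 2:(nx - 1)) {
    for (j in 2:(ny - 1)) {
      if (grid$mask[i, j] != 1L) next
      d[i, j] <- (grid$u[i, j] - grid$u[i - 1, j] +
                    grid$v[i, j] - grid$v[i, j - 1]) / grid$cell_size
    }
  }
  d
}

test_that("still air with no sources, diffusion or evaporation leaves dye unchanged", {
  g <- flow_grid(nx = 16, ny = 16, viscosity = 0, dye_diffusion = 0,
                 evaporation_rate = 0)
  g$dye[[1]][8, 8] <- 5
  g$dye[[2]][4, 11] <- 2.5
  g2 <- step_fluid(g)
  expect_identical(g2$dye, g$dye)
  expect_identical(g2$u, g$u)
})

test_that("projection drives divergence to near zero at high solver iterations", {
  g <- flow_grid(nx = 16, ny = 16, solver_iters = 200, n_channels = 1)
  w <- wind_source(cbind(4:6, 8), c(0.2, 0.05))
  for (k in 1:20) g <- step_fluid(g, winds = list(w))
  maxv <- max(abs(c(g$u, g$v)))
  expect_gt(maxv, 0.01)
  dv <- oracle_divergence(g)
  expect_lte(max(abs(dv), na.rm = TRUE) * g$cell_size, 1e-6 * maxv)
  # package divergence agrees with the independent oracle
  expect_equal(flow_divergence(g), dv, tolerance = 1e-12)
})

test_that("default solver iterations remove at least 90% of pre-projection divergence", {
  g <- flow_grid(nx = 16, ny = 16, solver_iters = 20, n_channels = 1)
  # a strongly divergent initial field
  set.seed(4)
  g$u <- matrix(runif(256, -0.2, 0.2), 16, 16)
  g$v <- matrix(runif(256, -0.2, 0.2), 16, 16)
  d0 <- max(abs(oracle_divergence(g)), na.rm = TRUE)
  g2 <- step_fluid(g)
  d1 <- max(abs(oracle_divergence(g2)), na.rm = TRUE)
  expect_lt(d1, 0.1 * d0)
})

test_that("mass budget in still air: total dye = injected source mass", {
  g <- flow_grid(nx = 20, ny = 20, viscosity = 0, dye_diffusion = 2e-4,
                 evaporation_rate = 0, solver_iters = 200, n_channels = 1)
  s <- plume_source(c(10, 10), channel = 1, rate = 50)
  for (k in 1:10) g <- step_fluid(g, sources = list(s))
  expected <- 10 * 50 * g$dt
  expect_equal(total_dye_mass(g), expected, tolerance = 1e-9)
})

test_that("evaporation decays dye mass by exp(-rate * dt) per step", {
  g <- flow_grid(nx = 16, ny = 16, viscosity = 0, dye_diffusion = 0,
                 evaporation_rate = 0.5, n_channels = 1)
  g$dye[[1]][8, 8] <- 10
  g2 <- step_fluid(g)
  expect_equal(total_dye_mass(g2), 10 * exp(-0.5 * g$dt), tolerance = 1e-12)
})

test_that("dye stays non-negative and fields finite over random forcing", {
  g <- flow_grid(nx = 16, ny = 16, n_channels = 2, evaporation_rate = 0.1)
  set.seed(11)
  for (k in 1:300) {
    w <- wind_source(cbind(sample(2:15, 2), sample(2:15, 2)),
                     runif(2, -0.3, 0.3))
    s <- plume_source(c(sample(2:15, 1), sample(2:15, 1)),
                      channel = sample(2, 1), rate = runif(1, 0, 80))
    g <- step_fluid(g, winds = list(w), sources = list(s))
  }
  for (d in g$dye) expect_true(all(d >= 0))
  expect_true(all(is.finite(c(g$u, g$v))))
})

test_that("scheme is stable at ten times the default time step", {
  g <- flow_grid(nx = 16, ny = 16, dt = 0.30, n_channels = 1)
  w <- wind_source(cbind(4:6, 8), c(0.2, 0.05))
  s <- plume_source(c(8, 8), channel = 1, rate = 50)
  for (k in 1:50) g <- step_fluid(g, winds = list(w), sources = list(s))
  expect_true(all(is.finite(c(g$u, g$v, g$dye[[1]]))))
})

test_that("identical grids and inputs give bit-identical fields", {
  run <- function() {
    g <- flow_grid(nx = 20, ny = 20, n_channels = 2)
    w <- wind_source(cbind(5:7, 10), c(0.1, 0.02))
    s <- plume_source(c(10, 10), channel = 1, rate = 30)
    for (k in 1:30) g <- step_fluid(g, winds = list(w), sources = list(s))
    g
  }
  a <- run(); b <- run()
  expect_identical(a$u, b$u)
  expect_identical(a$dye, b$dye)
})

test_that("robot leading-edge forces are equal and opposite to the stored flow", {
  g <- flow_grid(nx = 30, ny = 30, cell_size = 0.02, n_channels = 1)
  rb <- robot_state(position = c(0.3, 0.3), heading = 0)
  # still air: all forces zero
  f0 <- robot_perturbation_forces(g, rb)
  expect_true(all(f0$fx == 0) && all(f0$fy == 0))
  expect_gte(nrow(f0), ceiling(rb$width / g$cell_size))
  # uniform flow (0.2, 0): each force is (-0.2, 0) at magnitude 1
  g$u[] <- 0.2
  f1 <- robot_perturbation_forces(g, rb, magnitude = 1)
  expect_true(all(f1$fx == -0.2) && all(f1$fy == 0))
  # sum oracle: brute-force sum of -mag * velocity over returned cells
  set.seed(3)
  g$u <- matrix(runif(900, -1, 1), 30, 30)
  g$v <- matrix(runif(900, -1, 1), 30, 30)
  mag <- 0.7
  f2 <- robot_perturbation_forces(g, rb, magnitude = mag)
  sum_oracle_x <- -mag * sum(g$u[cbind(f2$i, f2$j)])
  sum_oracle_y <- -mag * sum(g$v[cbind(f2$i, f2$j)])
  expect_equal(sum(f2$fx), sum_oracle_x, tolerance = 1e-12)
  expect_equal(sum(f2$fy), sum_oracle_y, tolerance = 1e-12)
  # pose outside the grid errors
  rb_out <- robot_state(position = c(0.62, 0.3), heading = 0)
  expect_error(robot_perturbation_forces(g, rb_out), "outside")
})

test_that("concentration sampling is bilinear with the stated conventions", {
  g <- flow_grid(nx = 16, ny = 16, cell_size = 0.05, n_channels = 2)
  # cell-center identity
  g$dye[[1]][7, 9] <- 3.7
  p_center <- c((7 - 0.5) * 0.05, (9 - 0.5) * 0.05)
  expect_equal(sample_concentrations(g, p_center)[1], 3.7)
  # constant-field invariance
  g$dye[[2]][] <- 1.25
  expect_equal(sample_concentrations(g, c(0.31, 0.47))[2], 1.25)
  # hand bilinear midpoint: cells (5,5),(6,5) = 0 and (5,6),(6,6) = 4 -> 2
  g2 <- flow_grid(nx = 16, ny = 16, cell_size = 0.05, n_channels = 1)
  g2$dye[[1]][5, 6] <- 4; g2$dye[[1]][6, 6] <- 4
  expect_equal(sample_concentrations(g2, c(5 * 0.05, 5 * 0.05))[1], 2.0)
  # out-of-grid position errors
  expect_error(sample_concentrations(g, c(2, 0.1)), "outside")
})

test_that("configuration errors are caught", {
  g <- flow_grid(nx = 16, ny = 16, n_channels = 1)
  expect_error(step_fluid(g, sources = list(plume_source(c(40, 8), 1, 10))),
               "outside")
  expect_error(step_fluid(g, sources = list(plume_source(c(8, 8), 3, 10))),
               "channel")
  expect_error(step_fluid(g, winds = list(wind_source(cbind(99, 2), c(1, 0)))),
               "outside")
  expect_error(flow_grid(nx = 16, ny = 16,
                         obstacles = list(obstacle(10, 20, 2, 3))),
               "outside")
})

test_that("obstacles block flow: velocity stays zero inside solid cells", {
  g <- flow_grid(nx = 24, ny = 24, n_channels = 1,
                 obstacles = list(obstacle(12, 13, 6, 18)))
  w <- wind_source(cbind(4:6, 12), c(0.3, 0))
  for (k in 1:40) g <- step_fluid(g, winds = list(w))
  expect_true(all(g$dye[[1]][g$mask == 0L] == 0))
  expect_true(all(is.finite(c(g$u, g$v))))
  # dye cannot accumulate inside the obstacle
  s <- plume_source(c(5, 12), channel = 1, rate = 50)
  for (k in 1:40) g <- step_fluid(g, winds = list(w), sources = list(s))
  expect_true(all(g$dye[[1]][12:13, 6:18] == 0))
})
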