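test_that("single-motif dose-response reaches half activation at C = K/d", {
  s <- sensor(motifs = 3, K = 0.8)
  od <- odorant(degrees = c(0, 0, 0.4, rep(0, 7)))
  expect_identical(steady_state_activation(s, od, 0.8 / 0.4), 0.5)
  expect_identical(steady_state_activation(s, od, 0), 0)
  # monotone nondecreasing and saturating below 1
  Cs <- seq(0, 50, length.out = 200)
  As <- vapply(Cs, function(C) steady_state_activation(s, od, C), numeric(1))
  expect_true(all(diff(As) >= 0))
  expect_true(all(As < 1))
  expect_gt(As[200], 0.9)
})

test_that("multi-motif single-odorant form sums K/d over shared motifs", {
  # K1/d1 = 1 and K2/d2 = 3 -> at C = 4, A = 4 / (4 + 4) = 0.5
  s <- sensor(motifs = c(1, 2), K = c(0.5, 1.5))
  od <- odorant(degrees = c(0.5, 0.5, rep(0, 8)))
  expect_equal(steady_state_activation(s, od, 4), 0.5)
  # no shared motif -> 0, not an error
  od2 <- odorant(degrees = c(0, 0, 0, 1, rep(0, 6)))
  expect_identical(steady_state_activation(s, od2, 10), 0)
})

test_that("motif concentrations are concentration-times-degree sums", {
  od1 <- odorant(degrees = c(0.5, rep(0, 9)), channel = 1)
  expect_equal(motif_concentrations(2.0, list(od1)),
               c(1.0, rep(0, 9)))
  expect_equal(motif_concentrations(0, list(od1)), rep(0, 10))
  # two odorants sharing motif 3: contributions 0.4 and 0.6 sum to 1.0
  oda <- odorant(degrees = c(0, 0, 0.2, rep(0, 7)), channel = 1)
  odb <- odorant(degrees = c(0, 0, 0.3, rep(0, 7)), channel = 2)
  m <- motif_concentrations(c(2, 2), list(oda, odb))
  expect_equal(m[3], 0.4 + 0.6)
  # channel mismatch errors
  expect_error(motif_concentrations(2, list(odb)), "channel")
})

test_that("mixture activation is occupancy-based and reduces to the single-odorant form", {
  s <- sensor(motifs = 2, K = 0.7)
  expect_identical(mixture_activation(s, rep(0, 10)), 0)
  m <- rep(0, 10); m[2] <- 0.7
  expect_equal(mixture_activation(s, m), 0.5)
  # S contributions (0.25, 0.25) -> A = 0.5 / 1.5 = 1/3
  s2 <- sensor(motifs = c(1, 4), K = c(2, 4))
  m2 <- rep(0, 10); m2[1] <- 0.5; m2[4] <- 1
  expect_equal(mixture_activation(s2, m2), 1 / 3)
  # equals Eq.-style single form for one odorant with one motif
  od <- odorant(degrees = c(0.3, rep(0, 9)))
  for (C in c(0.1, 1, 7)) {
    expect_equal(mixture_activation(sensor(1, 0.9),
                                    motif_concentrations(C, list(od))),
                 steady_state_activation(sensor(1, 0.9), od, C))
  }
})

test_that("activation is monotone in every motif concentration (property)", {
  set.seed(21)
  for (rep in 1:50) {
    nm <- sample(1:4, 1)
    s <- sensor(motifs = sample(10, nm), K = runif(nm, 0.05, 5))
    m <- runif(10, 0, 3)
    a0 <- mixture_activation(s, m)
    k <- sample(10, 1)
    m2 <- m; m2[k] <- m2[k] + runif(1, 0, 2)
    expect_gte(mixture_activation(s, m2), a0)
    expect_lt(mixture_activation(s, m2), 1)
  }
})

test_that("kinetic updates converge to the closed-form fixed point", {
  rf <- 8; rb <- 2; dt <- 0.02; Abar <- 0.6
  A_star <- rf * Abar / (rf + rb)
  # fixed point is invariant
  expect_equal(kinetic_update(A_star, Abar, rf, rb, dt), A_star)
  # pure decay toward zero
  A <- 0.8
  for (k in 1:10) {
    A_new <- kinetic_update(A, 0, rf, rb, dt)
    expect_lt(A_new, A)
    A <- A_new
  }
  # discrete trajectory approaches the closed-form exponential solution
  A <- 0; lam <- rf + rb
  n <- ceiling(20 / (dt * lam))
  for (k in 1:n) A <- kinetic_update(A, Abar, rf, rb, dt)
  expect_equal(A, A_star, tolerance = 1e-6)
  # closed form of the ODE at finite time agrees to first order in dt
  A_euler <- 0
  for (k in 1:50) A_euler <- kinetic_update(A_euler, Abar, rf, rb, dt)
  A_exact <- A_star * (1 - exp(-lam * 50 * dt))
  expect_equal(A_euler, A_exact, tolerance = 0.05)
  # unstable dt triggers sub-stepping with a warning but stays in [0, 1]
  expect_warning(A2 <- kinetic_update(0.5, 1, 100, 50, 0.05), "sub-stepping")
  expect_true(A2 >= 0 && A2 <= 1)
})

test_that("fast kinetics recover the instantaneous steady state", {
  s <- sensor(motifs = 1, K = 1, r_f = 500, r_beta = 1)
  m <- rep(0, 10); m[1] <- 1
  target <- mixture_activation(s, m)
  A <- 0
  for (k in 1:200) A <- kinetic_update(A, target, 500, 1, 0.001)
  expect_equal(A, target * 500 / 501, tolerance = 1e-3)
})

test_that("sensor arrays are reproducible and structurally correct", {
  a1 <- generate_sensor_array(n_sensors = 1024, n_motifs = 10, seed = 5)
  a2 <- generate_sensor_array(n_sensors = 1024, n_motifs = 10, seed = 5)
  expect_identical(a1$affinities, a2$affinities)
  expect_equal(nrow(a1$affinities), 1024 * 3)
  expect_true(all(a1$affinities$motif %in% 1:10))
  expect_true(all(a1$affinities$K >= 0.05 & a1$affinities$K <= 5))
  # every sensor binds distinct motifs
  dup <- dplyr::count(a1$affinities, sensor, motif)
  expect_true(all(dup$n == 1))
  expect_error(generate_sensor_array(motifs_per_sensor = 20), "motifs")
})

test_that("motif usage frequencies match the binomial sampling oracle", {
  a <- generate_sensor_array(n_sensors = 10000, n_motifs = 10,
                             motifs_per_sensor = 3, seed = 9)
  counts <- table(factor(a$affinities$motif, levels = 1:10))
  p <- 3 / 10
  expected <- 10000 * p
  sd3 <- 3 * sqrt(10000 * p * (1 - p))
  expect_true(all(abs(counts - expected) <= sd3))
})

test_that("background contributes a constant offset when noise is zero", {
  bg <- background(list(odorant(c(0.2, 0.8, rep(0, 8)))),
                   mean_concentration = 0.5, noise_sd = 0)
  s1 <- sample_background(bg)
  s2 <- sample_background(bg)
  expect_identical(s1, s2)
  expect_equal(s1[1:2], c(0.1, 0.4))
  # noisy samples are clamped non-negative
  bg2 <- background(list(odorant(c(1, rep(0, 9)))),
                    mean_concentration = 0.01, noise_sd = 0.5)
  set.seed(2)
  draws <- replicate(50, sample_background(bg2)[1])
  expect_true(all(draws >= 0))
  expect_gt(stats::sd(draws), 0)
})
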