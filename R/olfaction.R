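#' Define an odorant as a vector of motif degrees
#'
#' Odorants are abstracted as the degree (0 to 1) to which they exhibit each
#' of a set of abstract molecular motifs (default 10). Sensors bind motifs,
#' not odorants: the concentration of motif `a` contributed by an odorant at
#' concentration `C` is `C * d_a`.
#'
#' @param degrees Numeric vector of motif degrees in `[0, 1]`, length =
#'   number of motifs; at least one must be positive.
#' @param channel Dye channel index carrying this odorant in the flow grid.
#' @param name Optional label.
#' @return An `odorant` object.
#' @export
odorant <- function(degrees, channel = 1L, name = NULL) {
  stopifnot(all(degrees >= 0), all(degrees <= 1), any(degrees > 0))
  structure(list(degrees = as.numeric(degrees), channel = as.integer(channel),
                 name = name), class = "odorant")
}

#' Define a single motif-binding sensor
#'
#' For sensor `i`, the affinity to motif `a` is the inverse of `K[a]`, the
#' motif concentration eliciting half-maximal activation. `r_f` and `r_beta`
#' are the first-order activation/deactivation rates used when the kinetic
#' mode is enabled; the default operating mode is instantaneous steady-state
#' activation.
#'
#' @param motifs Integer indices of motifs the sensor binds.
#' @param K Half-activation motif concentrations, same length as `motifs`,
#'   all positive.
#' @param r_f,r_beta Kinetic activation/deactivation rates (1/s).
#' @return A `sensor` object.
#' @export
sensor <- function(motifs, K, r_f = 50, r_beta = 10) {
  stopifnot(length(motifs) == length(K), all(K > 0), length(motifs) >= 1)
  structure(list(motifs = as.integer(motifs), K = as.numeric(K),
                 r_f = r_f, r_beta = r_beta), class = "sensor")
}

#' Motif concentrations of an odorant scene
#'
#' Sums `C_j * d_j` over the plume odorants (concentration per dye channel)
#' and any background motif vector, giving the motif concentrations that
#' drive the sensors.
#'
#' @param concentrations Per-channel odorant concentrations (e.g. from
#'   [sample_concentrations()]), all `>= 0`.
#' @param odorants List of [odorant()] objects; each must reference a
#'   channel present in `concentrations`.
#' @param background_sample Optional motif concentration vector to add
#'   (from [sample_background()]).
#' @return Motif concentration vector `m >= 0`.
#' @export
motif_concentrations <- function(concentrations, odorants,
                                 background_sample = NULL) {
  if (any(concentrations < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  n_motifs <- length(odorants[[1]]$degrees)
  m <- numeric(n_motifs)
  for (od in odorants) {
    stopifnot(inherits(od, "odorant"))
    if (od$channel > length(concentrations))
      stop("odorant channel has no matching concentration entry",
           call. = FALSE)
    m <- m + concentrations[od$channel] * od$degrees
  }
  if (!is.null(background_sample)) m <- m + background_sample
  m
}

#' Steady-state activation of a sensor by a single odorant
#'
#' The printed single-odorant dose-response forms, evaluated verbatim. With
#' one shared motif, `A = C*d / (C*d + K)`, so `A = 0.5` exactly at
#' `C = K / d`. With several shared motifs, `A = C / (C + sum(K/d))` over
#' the motifs the odorant and sensor share. A sensor sharing no motif with
#' the odorant returns 0. For multi-odorant scenes use
#' [mixture_activation()].
#'
#' @param sens A [sensor()].
#' @param odor An [odorant()] evaluated in isolation.
#' @param C Odorant concentration, `>= 0`.
#' @return Activation in `[0, 1)`, monotone nondecreasing in `C`.
#' @export
steady_state_activation <- function(sens, odor, C) {
  stopifnot(inherits(sens, "sensor"), inherits(odor, "odorant"), C >= 0)
  d <- odor$degrees[sens$motifs]
  shared <- d > 0
  if (!any(shared)) return(0)
  if (sum(shared) == 1) {
    cd <- C * d[shared]
    cd / (cd + sens$K[shared])
  } else {
    C / (C + sum(sens$K[shared] / d[shared]))
  }
}

#' Activation of a sensor by a motif concentration mixture
#'
#' Each bound motif occupies an independent first-order receptor; occupancies
#' combine linearly and jointly activate the sensor:
#' `S = sum(m_a / K_a)` over the sensor's motifs and `A = S / (1 + S)`.
#' For a single odorant carrying a single motif this reduces exactly to the
#' single-odorant form of [steady_state_activation()].
#'
#' @param sens A [sensor()].
#' @param m Motif concentration vector (full length, `>= 0`).
#' @return Activation in `[0, 1)`, monotone in every `m_a`.
#' @export
mixture_activation <- function(sens, m) {
  stopifnot(inherits(sens, "sensor"), all(m >= 0))
  S <- sum(m[sens$motifs] / sens$K)
  S / (1 + S)
}

#' One kinetic update of sensor activation
#'
#' Explicit-Euler step of `dA/dt = r_f * (A_target - A) - r_beta * A`, whose
#' fixed point is `A* = r_f * A_target / (r_f + r_beta)`. If
#' `dt * (r_f + r_beta) > 1` the step is sub-divided (with a warning) so the
#' update remains stable and `A` stays in `[0, 1]`.
#'
#' @param A Current activation(s).
#' @param A_target Equilibrium activation(s) (from the steady-state forms).
#' @param r_f,r_beta Activation/deactivation rates (1/s), `>= 0`.
#' @param dt Time step (s), `> 0`.
#' @return Updated activation(s).
#' @export
kinetic_update <- function(A, A_target, r_f, r_beta, dt) {
  stopifnot(r_f >= 0, r_beta >= 0, dt > 0)
  n_sub <- 1L
  if (dt * (r_f + r_beta) > 1) {
    n_sub <- as.integer(ceiling(dt * (r_f + r_beta)))
    warning(sprintf(
      "dt * (r_f + r_beta) = %.3g > 1; sub-stepping kinetic update %d-fold",
      dt * (r_f + r_beta), n_sub))
  }
  h <- dt / n_sub
  for (k in seq_len(n_sub)) A <- A + h * (r_f * (A_target - A) - r_beta * A)
  A
}

#' Generate a random sensor array
#'
#' Each of `n_sensors` sensors binds `motifs_per_sensor` distinct motifs
#' chosen uniformly at random from the `n_motifs` available, with
#' half-activation concentrations `K` drawn log-uniformly from `K_range`.
#' Deterministic under `seed`.
#'
#' @param n_sensors Number of sensors (default 1024; 256 is the smaller
#'   standard array).
#' @param n_motifs Number of motifs (default 10).
#' @param motifs_per_sensor Motifs bound per sensor.
#' @param K_range Length-2 positive range for log-uniform `K` draws.
#' @param seed Integer seed.
#' @return A `sensor_array`: affinity tibble (`sensor`, `motif`, `K`), the
#'   `n_sensors x n_motifs` inverse-affinity matrix used for fast mixture
#'   activation, and the generation parameters.
#' @export
generate_sensor_array <- function(n_sensors = 1024, n_motifs = 10,
                                  motifs_per_sensor = 3,
                                  K_range = c(0.05, 5), seed = 1) {
  stopifnot(motifs_per_sensor >= 1, motifs_per_sensor <= n_motifs,
            length(K_range) == 2, all(K_range > 0), K_range[1] < K_range[2])
  with_seed(seed, {
    motifs <- t(vapply(seq_len(n_sensors), function(i)
      sample.int(n_motifs, motifs_per_sensor), integer(motifs_per_sensor)))
    K <- exp(matrix(runif(n_sensors * motifs_per_sensor,
                          log(K_range[1]), log(K_range[2])),
                    n_sensors, motifs_per_sensor))
  })
  inv_K <- matrix(0, n_sensors, n_motifs)
  idx <- cbind(rep(seq_len(n_sensors), motifs_per_sensor), as.vector(motifs))
  inv_K[idx] <- 1 / as.vector(K)
  affinities <- tibble::tibble(
    sensor = rep(seq_len(n_sensors), each = motifs_per_sensor),
    motif = as.vector(t(motifs)),
    K = as.vector(t(K))
  )
  structure(list(
    n_sensors = n_sensors, n_motifs = n_motifs,
    motifs_per_sensor = motifs_per_sensor, K_range = K_range, seed = seed,
    affinities = affinities, inv_K = inv_K
  ), class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d sensors x %d motifs (%d per sensor), seed %s\n",
              x$n_sensors, x$n_motifs, x$motifs_per_sensor, x$seed))
  invisible(x)
}

#' Extract one sensor from a sensor array
#'
#' @param array A [generate_sensor_array()] result.
#' @param i Sensor index.
#' @return A [sensor()].
#' @export
array_sensor <- function(array, i) {
  rows <- array$affinities[array$affinities$sensor == i, ]
  sensor(rows$motif, rows$K)
}

#' Activations of a whole sensor array for a motif mixture
#'
#' Vectorized [mixture_activation()] over all sensors in the array.
#'
#' @param array A [generate_sensor_array()] result.
#' @param m Motif concentration vector, length `n_motifs`.
#' @return Numeric vector of `n_sensors` activations in `[0, 1)`.
#' @export
array_activations <- function(array, m) {
  if (length(m) != array$n_motifs || any(m < 0))
    stop("motif vector must be non-negative with length n_motifs",
         call. = FALSE)
  S <- as.vector(array$inv_K %*% m)
  S / (1 + S)
}

#' Define a stochastic background odor environment
#'
#' The background is a set of odorants, constant in space and time except
#' for zero-mean Gaussian variation redrawn each CFD step; sampled
#' concentrations are clamped at zero. It is applied at the sensor as an
#' added motif concentration, not as a dye channel.
#'
#' @param odorants List of [odorant()] objects.
#' @param mean_concentration Mean concentration per background odorant
#'   (recycled), `>= 0`.
#' @param noise_sd Per-sample Gaussian SD (0 gives a constant offset).
#' @return A `background` object for [sample_background()].
#' @export
background <- function(odorants, mean_concentration = 0.1, noise_sd = 0.02) {
  stopifnot(all(mean_concentration >= 0), noise_sd >= 0)
  mean_concentration <- rep_len(mean_concentration, length(odorants))
  structure(list(odorants = odorants,
                 mean_concentration = mean_concentration,
                 noise_sd = noise_sd), class = "background")
}

#' Draw one background motif-concentration sample
#'
#' @param bg A [background()], or `NULL` (returns `NULL`).
#' @return Motif concentration vector, or `NULL`.
#' @export
sample_background <- function(bg) {
  if (is.null(bg)) return(NULL)
  n_motifs <- length(bg$odorants[[1]]$degrees)
  m <- numeric(n_motifs)
  for (k in seq_along(bg$odorants)) {
    C <- max(0, bg$mean_concentration[k] + rnorm(1, 0, bg$noise_sd))
    m <- m + C * bg$odorants[[k]]$degrees
  }
  m
}

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}
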