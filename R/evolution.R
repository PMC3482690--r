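#' Genome schema: the evolvable parameters and their bounds
#'
#' Version 1 of the schema names 31 bounded parameters: for each of the five
#' synapse classes an additive weight, a PSP (box-car) duration in
#' timesteps, a depression fraction `U` and a recovery rate; the branch and
#' soma homeostatic target rates; the branch count required to fire the
#' soma (`n_b`); the sigmoidal branch gain; initial branch/soma thresholds
#' and the interneuron/motor unit thresholds; the motor output gain; and
#' the sensor kinetic rates. The inhibitory class weight is stored as a
#' magnitude and applied negatively.
#'
#' @return Tibble with columns `name`, `lo`, `hi`, `default`.
#' @export
genome_schema <- function() {
  cls <- c("sensor_mitral", "mitral_inter", "mitral_cortex",
           "inter_cortex", "cortex_motor")
  # bounds chosen so the feedforward excitation/inhibition balance of a
  # random draw usually leaves the cortex excitable (16 E vs 4 I per branch)
  w_lo <- c(0.2, 0.2, 0.02, 0.02, 0.02)
  w_hi <- c(4, 4, 0.6, 0.8, 1)
  w_def <- c(1.5, 1.5, 0.12, 0.2, 0.1)
  tb <- dplyr::bind_rows(
    tibble::tibble(name = paste0("w_", cls), lo = w_lo, hi = w_hi,
                   default = w_def),
    tibble::tibble(name = paste0("psp_", cls), lo = 1, hi = 6, default = 2),
    tibble::tibble(name = paste0("u_", cls), lo = 0, hi = 0.8,
                   default = 0.2),
    tibble::tibble(name = paste0("rec_", cls), lo = 0.01, hi = 0.5,
                   default = 0.1),
    tibble::tribble(
      ~name, ~lo, ~hi, ~default,
      "branch_target", 0.02, 0.4, 0.1,
      "soma_target",   0.02, 0.4, 0.1,
      "n_b",           1,    8,   2,
      "branch_gain",   0.5,  8,   4,
      "theta_int",     0.05, 2,   0.3,
      "theta_m",       0.1,  10,  1,
      "theta_b0",      0.05, 3,   0.5,
      "theta_s0",      0.5,  8,   2,
      "motor_gain",    0.5,  2,   1,
      "sensor_rf",     5,    200, 50,
      "sensor_rbeta",  0.5,  50,  10
    )
  )
  attr(tb, "schema_version") <- 1L
  tb
}

#' Construct a genome from named values
#'
#' @param values Named numeric vector; must cover every schema parameter
#'   and respect its bounds.
#' @param schema A [genome_schema()].
#' @return A `genome` object.
#' @export
genome <- function(values, schema = genome_schema()) {
  values <- unlist(values)
  missing <- setdiff(schema$name, names(values))
  if (length(missing))
    stop("genome missing parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  values <- values[schema$name]
  bad <- values < schema$lo | values > schema$hi
  if (any(bad))
    stop("genome values out of bounds: ",
         paste(schema$name[bad], collapse = ", "), call. = FALSE)
  structure(list(values = values, schema_version =
                   attr(schema, "schema_version") %||% 1L),
            class = "genome")
}

#' Default genome (schema defaults)
#'
#' @param schema A [genome_schema()].
#' @return A `genome`.
#' @export
default_genome <- function(schema = genome_schema()) {
  genome(setNames(schema$default, schema$name), schema)
}

#' Draw a random genome uniformly within bounds
#'
#' Uses the current RNG stream (seed with [with_seed()] or `set.seed()`).
#'
#' @param schema A [genome_schema()].
#' @return A `genome`.
#' @export
random_genome <- function(schema = genome_schema()) {
  genome(setNames(runif(nrow(schema), schema$lo, schema$hi), schema$name),
         schema)
}

#' Named parameter values of a genome
#'
#' @param g A `genome` or named numeric vector.
#' @return Named numeric vector.
#' @export
genome_values <- function(g) {
  if (inherits(g, "genome")) g$values
  else if (is.numeric(g) && !is.null(names(g))) g
  else stop("expected a genome or named numeric vector", call. = FALSE)
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> schema v%d, %d parameters\n", x$schema_version,
              length(x$values)))
  invisible(x)
}

#' Derive a sub-seed from a master seed
#'
#' Deterministic integer hash of the master seed and any index components
#' (generation, individual, trial), kept below 2^31 so per-individual
#' evaluation is independent of scheduling order.
#'
#' @param master Master seed.
#' @param ... Integer components.
#' @return Positive integer seed.
#' @export
derive_seed <- function(master, ...) {
  x <- as.numeric(master) %% 2147483647
  for (k in c(...)) {
    x <- (x * 48271 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(x + 1)
}

#' Time-to-source fitness of a genome (lower is better)
#'
#' Builds the network from the genome (wiring seeded by the scenario seed),
#' runs closed-loop trials, and scores each trial by the time to reach the
#' target proximity, or — when the source is not reached — by `T_max` plus
#' the final distance normalized by the world diagonal (keeping a selection
#' gradient among unsuccessful individuals). Trials are averaged; an
#' aborted trial scores `T_max + 1` with a diagnostic warning.
#'
#' @param g A genome.
#' @param scn A [scenario()].
#' @param seed Evaluation seed; per-trial seeds are derived from it.
#' @param net_config A [network_config()].
#' @param array Sensor array matching `net_config` (built from the scenario
#'   seed when `NULL`).
#' @param trials Trials per individual.
#' @param initial_grid Optional shared pre-warmed grid.
#' @param wiring Optional shared wiring tables (see [build_network()]).
#' @return Scalar fitness.
#' @export
fitness <- function(g, scn, seed = 1, net_config = network_config_desk(),
                    array = NULL, trials = 1, initial_grid = NULL,
                    wiring = NULL) {
  if (is.null(array))
    array <- generate_sensor_array(n_sensors = net_config$n_sensors,
                                   seed = scn$seed)
  walls_diag <- {
    b <- scenario_walls(scn)$bounds
    sqrt((b[3] - b[1])^2 + (b[4] - b[2])^2)
  }
  net <- build_network(g, net_config, seed = scn$seed, wiring = wiring)
  ctrl <- neural_controller(net, array, scn$odorants, bg = scn$bg)
  vals <- vapply(seq_len(trials), function(k) {
    res <- tryCatch(
      run_trial(scn, ctrl, seed = derive_seed(seed, k),
                initial_grid = initial_grid, log = FALSE),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("trial aborted: ", conditionMessage(res))
      return(scn$max_duration + 1)
    }
    if (res$reached) res$time_to_source
    else scn$max_duration + res$final_distance / walls_diag
  }, numeric(1))
  mean(vals)
}

#' Evolution run configuration
#'
#' Desk defaults: population 16 over 20 generations with tournament
#' selection, uniform crossover, per-gene Gaussian mutation clipped to
#' bounds (with a gentle annealing schedule), elitism 1 and one trial per
#' individual. The defaults lean toward strong exploitation (large
#' tournament, frequent mutation, decaying step size) because desk runs
#' afford only a few hundred evaluations; full-scale runs with populations
#' of 100-150 over 100-150 generations can relax the selection pressure.
#'
#' @param population Individuals per generation (>= 2).
#' @param generations Number of generations.
#' @param mutation_p Per-gene mutation probability.
#' @param mutation_sigma Gaussian mutation SD as a fraction of each gene's
#'   range (at generation 1).
#' @param mutation_decay Multiplicative per-generation decay of the
#'   mutation SD (annealing schedule); 1 keeps it fixed.
#' @param crossover_p Probability a child is a uniform crossover of two
#'   parents (else a copy of the first).
#' @param tournament Tournament size for selection.
#' @param elitism Best individuals copied unchanged (< population).
#' @param trials Trials per fitness evaluation.
#' @param seed Master seed.
#' @return An `evolution_config` list.
#' @export
evolution_config <- function(population = 16, generations = 20,
                             mutation_p = 0.4, mutation_sigma = 0.15,
                             mutation_decay = 0.95, crossover_p = 0.9,
                             tournament = 12, elitism = 1, trials = 1,
                             seed = 1) {
  stopifnot(population >= 2, elitism < population, generations >= 1,
            tournament >= 1, mutation_decay > 0, mutation_decay <= 1)
  structure(as.list(environment()), class = "evolution_config")
}

#' Produce the next generation
#'
#' Elitism copies the best individuals unchanged; remaining slots are
#' filled by tournament selection, uniform crossover, and per-gene
#' Gaussian mutation clipped to the schema bounds. Deterministic under the
#' current RNG stream.
#'
#' @param population List of genomes.
#' @param fitnesses Numeric vector (lower is better), same length.
#' @param config An [evolution_config()].
#' @param schema A [genome_schema()].
#' @param sigma_scale Scale applied to the mutation SD (the annealing
#'   schedule supplies `mutation_decay^(generation - 1)`).
#' @return List of genomes, same size as `population`.
#' @export
next_generation <- function(population, fitnesses,
                            config = evolution_config(),
                            schema = genome_schema(), sigma_scale = 1) {
  stopifnot(length(population) == length(fitnesses))
  n <- length(population)
  ord <- order(fitnesses)
  out <- vector("list", n)
  n_elite <- min(config$elitism, n)
  for (e in seq_len(n_elite)) out[[e]] <- population[[ord[e]]]
  pick <- function() {
    cand <- sample.int(n, min(config$tournament, n))
    population[[cand[which.min(fitnesses[cand])]]]
  }
  rng_range <- schema$hi - schema$lo
  for (k in seq(n_elite + 1, length.out = n - n_elite)) {
    p1 <- genome_values(pick())
    child <- p1
    if (runif(1) < config$crossover_p) {
      p2 <- genome_values(pick())
      take2 <- runif(length(child)) < 0.5
      child[take2] <- p2[take2]
    }
    mut <- runif(length(child)) < config$mutation_p
    if (any(mut)) {
      child[mut] <- child[mut] +
        rnorm(sum(mut), 0,
              sigma_scale * config$mutation_sigma * rng_range[mut])
      child <- pmin(pmax(child, schema$lo), schema$hi)
    }
    out[[k]] <- genome(child, schema)
  }
  out
}

#' Run an artificial evolution
#'
#' Evaluates each generation's individuals independently (per-individual
#' seeds are hashes of the master seed, generation and index, so results do
#' not depend on evaluation order), selects parents by relative fitness,
#' and iterates. Fully reproducible from the master seed. When
#' `checkpoint_dir` is given, per-generation state is written as JSON and
#' an interrupted run resumes from the last completed generation.
#'
#' @param config An [evolution_config()].
#' @param scn A [scenario()] defining the trial world.
#' @param net_config A [network_config()] for the evolved circuits.
#' @param schema A [genome_schema()].
#' @param fitness_fn Fitness override `function(genome, seed)` (used for
#'   algorithm tests on analytic landscapes); default is the closed-loop
#'   [fitness()].
#' @param checkpoint_dir Optional directory for resumable checkpoints.
#' @param quiet Suppress per-generation progress messages.
#' @return An `evolution_history`: per-generation per-individual fitness
#'   tibble, best genome per generation, and the run configuration.
#' @export
run_evolution <- function(config = evolution_config(), scn = NULL,
                          net_config = network_config_desk(),
                          schema = genome_schema(), fitness_fn = NULL,
                          checkpoint_dir = NULL, quiet = TRUE) {
  master <- config$seed
  if (is.null(fitness_fn)) {
    stopifnot(inherits(scn, "scenario"))
    array <- generate_sensor_array(n_sensors = net_config$n_sensors,
                                   seed = scn$seed)
    grid0 <- warmup_grid(scn)
    wiring0 <- build_network(default_genome(schema), net_config,
                             seed = scn$seed)$wiring
    fitness_fn <- function(g, seed)
      fitness(g, scn, seed = seed, net_config = net_config, array = array,
              trials = config$trials, initial_grid = grid0,
              wiring = wiring0)
  }

  start_gen <- 1L
  pop <- NULL
  records <- list()
  best_genomes <- list()
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
    ck <- file.path(checkpoint_dir, "checkpoint.json")
    if (file.exists(ck)) {
      state <- jsonlite::read_json(ck, simplifyVector = TRUE)
      if (identical(as.integer(state$master), as.integer(master))) {
        start_gen <- state$next_gen
        pop <- lapply(seq_len(nrow(state$pop)), function(i)
          genome(setNames(as.numeric(state$pop[i, ]),
                          colnames(state$pop)), schema))
        records <- list(tibble::as_tibble(state$records))
        bst <- state$best
        if (is.data.frame(bst)) {
          best_genomes <- lapply(seq_len(nrow(bst)), function(i)
            genome(unlist(bst[i, ]), schema))
        } else {
          best_genomes <- lapply(bst, function(b) genome(unlist(b), schema))
        }
      }
    }
  }
  if (is.null(pop)) {
    pop <- with_seed(derive_seed(master, 0L), {
      lapply(seq_len(config$population), function(i) random_genome(schema))
    })
  }

  for (gen in seq(start_gen, config$generations)) {
    fits <- vapply(seq_along(pop), function(i)
      fitness_fn(pop[[i]], derive_seed(master, gen, i)), numeric(1))
    records[[length(records) + 1]] <- tibble::tibble(
      generation = gen, individual = seq_along(pop), fitness = fits,
      seed = vapply(seq_along(pop), function(i)
        derive_seed(master, gen, i), integer(1)))
    best_genomes[[gen]] <- pop[[which.min(fits)]]
    if (!quiet)
      message(sprintf("generation %d: best %.4f median %.4f", gen,
                      min(fits), median(fits)))
    # always advance the population (checkpoints must store the selected
    # next generation so resumed runs replay identically)
    decay <- config$mutation_decay %||% 1
    pop <- with_seed(derive_seed(master, gen, 999999L), {
      next_generation(pop, fits, config, schema,
                      sigma_scale = decay^(gen - 1))
    })
    if (!is.null(checkpoint_dir)) {
      hist_so_far <- dplyr::bind_rows(records)
      state <- list(
        master = master, next_gen = gen + 1L,
        pop = as.data.frame(do.call(rbind, lapply(pop, genome_values))),
        records = hist_so_far,
        best = lapply(best_genomes, function(g) as.list(genome_values(g))))
      jsonlite::write_json(state, file.path(checkpoint_dir,
                                            "checkpoint.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  structure(list(
    history = dplyr::bind_rows(records),
    best_genomes = best_genomes,
    config = config,
    schema_version = attr(schema, "schema_version") %||% 1L
  ), class = "evolution_history")
}

#' @export
print.evolution_history <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<evolution_history> %d individuals x %d generations; best fitness %.4f (gen-0 median %.4f)\n",
    x$config$population, max(x$history$generation), g$best_fitness,
    g$gen0_median))
  invisible(x)
}
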