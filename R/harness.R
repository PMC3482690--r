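#' Generate a named scenario fixture
#'
#' Ready-made scenario presets, deterministic under `(name, seed, scale)`:
#'
#' * `"three-plume"`: three independent plume sources on distinct odorant
#'   channels (rendered red, green and blue in the interactive world) plus
#'   one wind source.
#' * `"two-plume-room"`: two plumes, two wind sources and one internal boundary —
#'   the classic enclosed-room layout.
#' * `"corridor"`: an obstacle-free single-plume corridor for kinematics
#'   and scripted-controller tests.
#' * `"chase"`: the evolution trial world — one target plume carried by a
#'   steady wind toward the robot start, short trial cap, used by
#'   [run_evolution()] at desk scale.
#'
#' The `"full"` scale uses the 140 x 140 interactive grid; `"desk"` halves
#' it to 70 x 70 for fast closed-loop work.
#'
#' @param name Preset name.
#' @param seed Scenario seed.
#' @param scale `"full"` or `"desk"`.
#' @return A [scenario()].
#' @export
generate_fixture <- function(name = c("three-plume", "two-plume-room", "corridor",
                                      "chase"),
                             seed = 1, scale = c("full", "desk")) {
  if (!is.character(name) || !name[1] %in% c("three-plume", "two-plume-room",
                                             "corridor", "chase"))
    stop("unknown preset '", name[1],
         "'; available: three-plume, two-plume-room, corridor, chase",
         call. = FALSE)
  name <- name[1]
  scale <- match.arg(scale)
  n <- if (scale == "full") 140L else 70L
  h <- 0.02
  cx <- function(f) as.integer(round(f * n))   # fractional -> cell index
  grid3 <- list(nx = n, ny = n, cell_size = h, dt = 0.030,
                viscosity = 1e-5, dye_diffusion = 1e-5,
                evaporation_rate = 0.02,
                solver_iters = if (scale == "full") 20L else 10L,
                n_channels = 3L)
  od3 <- list(
    odorant(c(1, 0.6, rep(0, 8)), channel = 1, name = "red"),
    odorant(c(0, 0.2, 1, 0.5, rep(0, 6)), channel = 2, name = "green"),
    odorant(c(rep(0, 4), 0.8, 1, 0.3, rep(0, 3)), channel = 3,
            name = "blue"))

  wind_block <- function(f1, f2, force) {
    cells <- expand.grid(x = cx(f1[1]):cx(f2[1]), y = cx(f1[2]):cx(f2[2]))
    wind_source(as.matrix(cells), force)
  }

  scn <- switch(name,
    "three-plume" = scenario(
      grid = grid3,
      sources = list(
        plume_source(c(cx(0.25), cx(0.7)), channel = 1, rate = 50),
        plume_source(c(cx(0.5), cx(0.25)), channel = 2, rate = 50),
        plume_source(c(cx(0.75), cx(0.7)), channel = 3, rate = 50)),
      winds = list(wind_block(c(0.1, 0.45), c(0.12, 0.55), c(0.02, 0))),
      odorants = od3,
      robot_start = list(x = 0.5 * n * h, y = 0.5 * n * h, heading = 0),
      target_source = 1, proximity_radius = 0.15,
      max_duration = 30, warmup_steps = 150, seed = seed,
      name = "three-plume"),
    "two-plume-room" = scenario(
      grid = grid3,
      sources = list(
        plume_source(c(cx(0.2), cx(0.75)), channel = 1, rate = 50),
        plume_source(c(cx(0.8), cx(0.75)), channel = 3, rate = 50)),
      winds = list(
        wind_block(c(0.15, 0.2), c(0.18, 0.25), c(0.01, 0.02)),
        wind_block(c(0.8, 0.2), c(0.83, 0.25), c(-0.01, 0.02))),
      obstacles = list(obstacle(cx(0.5), cx(0.5) + 1L,
                                cx(0.3), cx(0.7))),
      odorants = od3,
      robot_start = list(x = 0.5 * n * h, y = 0.3 * n * h, heading = 0),
      target_source = 1, proximity_radius = 0.15,
      max_duration = 30, warmup_steps = 150, seed = seed,
      name = "two-plume-room"),
    "corridor" = scenario(
      grid = utils::modifyList(grid3, list(n_channels = 1L)),
      sources = list(plume_source(c(cx(0.85), cx(0.5)), channel = 1,
                                  rate = 50)),
      winds = list(),
      odorants = list(odorant(c(1, rep(0, 9)), channel = 1)),
      robot_start = list(x = 0.15 * n * h, y = 0.5 * n * h, heading = 0),
      target_source = 1, proximity_radius = 0.1,
      max_duration = 30, warmup_steps = 0, seed = seed,
      name = "corridor"),
    "chase" = scenario(
      grid = utils::modifyList(grid3, list(n_channels = 1L, viscosity = 0,
                                           dye_diffusion = 0,
                                           solver_iters = 8L)),
      sources = list(plume_source(c(cx(0.25), cx(0.5)), channel = 1,
                                  rate = 50)),
      winds = list(wind_block(c(0.1, 0.45), c(0.14, 0.55), c(0.03, 0))),
      odorants = list(odorant(c(1, 0.5, rep(0, 8)), channel = 1)),
      robot_start = list(x = 0.42 * n * h, y = 0.5 * n * h,
                         heading = pi),
      target_source = 1, proximity_radius = 0.12,
      max_duration = 4.2, warmup_steps = 150, seed = seed,
      name = "chase")
  )
  scn
}

scenario_to_list <- function(scn) {
  list(
    name = scn$name,
    grid = scn$grid,
    sources = lapply(scn$sources, function(s)
      list(cell = s$cell, channel = s$channel, rate = s$rate)),
    winds = lapply(scn$winds, function(w)
      list(cells = apply(w$cells, 1, function(r) as.list(r),
                         simplify = FALSE),
           force = w$force, strength = w$strength)),
    obstacles = lapply(scn$obstacles, function(ob) unclass(ob)),
    odorants = lapply(scn$odorants, function(od)
      list(degrees = od$degrees, channel = od$channel, name = od$name)),
    robot_start = scn$robot_start,
    robot = scn$robot,
    target_source = scn$target_source,
    proximity_radius = scn$proximity_radius,
    max_duration = scn$max_duration,
    warmup_steps = scn$warmup_steps,
    neural_steps_per_cfd_step = scn$neural_steps_per_cfd_step,
    seed = scn$seed,
    behavior = unclass(scn$behavior)
  )
}

#' Write / read a scenario as YAML
#'
#' Scenario files round-trip through the package's own reader: the
#' re-loaded scenario produces identical trials.
#'
#' @param scn A [scenario()].
#' @param path File path.
#' @return `write_scenario_yaml()`: `path`, invisibly;
#'   `read_scenario_yaml()`: a [scenario()].
#' @export
write_scenario_yaml <- function(scn, path) {
  yaml::write_yaml(scenario_to_list(scn), path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  scenario(
    grid = x$grid,
    sources = lapply(x$sources, function(s)
      plume_source(unlist(s$cell), s$channel, s$rate)),
    winds = lapply(x$winds, function(w)
      wind_source(do.call(rbind, lapply(w$cells, unlist)),
                  unlist(w$force), w$strength)),
    obstacles = lapply(x$obstacles, function(ob)
      obstacle(ob$x0, ob$x1, ob$y0, ob$y1)),
    odorants = lapply(x$odorants, function(od)
      odorant(unlist(od$degrees), od$channel, od$name)),
    robot_start = x$robot_start,
    robot = x$robot,
    target_source = x$target_source,
    proximity_radius = x$proximity_radius,
    max_duration = x$max_duration,
    warmup_steps = x$warmup_steps,
    neural_steps_per_cfd_step = x$neural_steps_per_cfd_step,
    seed = x$seed,
    behavior = do.call(behavior_params,
                       x$behavior[names(x$behavior) %in%
                                    names(formals(behavior_params))]),
    name = x$name
  )
}

#' Write the per-step concentration trace of a trial
#'
#' CSV with one row per CFD step (row spacing `dt`, 1/30 s at defaults):
#' time, raw per-channel concentrations at the sensor, and the same values
#' normalized by the per-channel maximum concentration found at the odor
#' source over the trial.
#'
#' @param result A [run_trial()] result with logs.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_concentration_trace <- function(result, path) {
  stopifnot(inherits(result, "trial_result"))
  if (is.null(result$concentrations))
    stop("trial was run with log = FALSE", call. = FALSE)
  cc <- result$concentrations
  K <- ncol(cc) - 1
  norm <- result$source_max
  norm[norm <= 0] <- 1
  nn <- as.data.frame(Map(function(k) cc[[k + 1]] / norm[k], seq_len(K)))
  names(nn) <- paste0("norm_c", seq_len(K))
  out <- dplyr::bind_cols(cc, tibble::as_tibble(nn))
  tryCatch(readr::write_csv(out, path),
           error = function(e)
             stop("failed writing concentration trace to '", path, "': ",
                  conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Write the trajectory log of a trial
#'
#' CSV columns: `t, x, y, heading, I_L, I_R, proximity`.
#'
#' @inheritParams write_concentration_trace
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(result, path) {
  stopifnot(inherits(result, "trial_result"))
  if (is.null(result$trajectory))
    stop("trial was run with log = FALSE", call. = FALSE)
  readr::write_csv(result$trajectory, path)
  invisible(path)
}

#' Write / read a genome as JSON
#'
#' @param g A [genome()].
#' @param path File path.
#' @return `write_genome_json()`: `path` invisibly; `read_genome_json()`:
#'   a [genome()].
#' @export
write_genome_json <- function(g, path) {
  stopifnot(inherits(g, "genome"))
  jsonlite::write_json(list(schema_version = g$schema_version,
                            values = as.list(g$values)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_genome_json
#' @export
read_genome_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  genome(unlist(x$values))
}

#' Write a reproducibility manifest
#'
#' Records the resolved configuration, its hash, the seeds and the package
#' version — sufficient to reproduce a run bit-exactly.
#'
#' @param path Output JSON path.
#' @param config Named list of resolved configuration values.
#' @param seeds Named list or vector of seeds used.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seeds) {
  jsonlite::write_json(list(
    package = "plumebot",
    version = as.character(utils::packageVersion("plumebot")),
    r_version = as.character(getRversion()),
    config_hash = rlang::hash(config),
    config = config,
    seeds = as.list(seeds),
    created = format(Sys.time(), tz = "UTC")
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
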