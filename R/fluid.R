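#' Create a 2-D stable-fluids grid with odorant dye channels
#'
#' The flow grid is the state of the plume world: a per-cell velocity field
#' plus one non-negative "dye" concentration field per odorant channel,
#' advanced by [step_fluid()] with the classic stable-fluids pipeline
#' (implicit diffusion, semi-Lagrangian advection, pressure projection),
#' which is unconditionally stable for any time step.
#'
#' Cells are square with side `cell_size` metres; cell `(1, 1)` sits at the
#' lower-left corner and world position `(x, y)` in metres maps to cell
#' `(floor(x / cell_size) + 1, floor(y / cell_size) + 1)` (half-open cell
#' intervals). The outermost ring of cells is always solid wall; internal
#' boundaries are added with `obstacles`. Velocity is stored per cell on a
#' staggered (marker-and-cell) layout — `u[i, j]` is the x-component on the
#' east face of cell `(i, j)`, `v[i, j]` the y-component on its north face —
#' which lets the projection drive the discrete divergence to the solver
#' residual exactly; dye fields are cell-centered.
#'
#' @param nx,ny Cell counts including the one-cell wall ring (default
#'   140 x 140).
#' @param cell_size Metres per cell.
#' @param dt Seconds advanced per CFD step (default 0.030 s).
#' @param viscosity Momentum diffusion coefficient (m^2/s).
#' @param dye_diffusion Dye diffusion coefficient (m^2/s).
#' @param evaporation_rate First-order dye decay rate (1/s), applied as
#'   `dye * exp(-rate * dt)` after advection.
#' @param solver_iters Gauss-Seidel sweeps for the diffusion and pressure
#'   solves (default 20, interactive fidelity; use 200 for tight projection).
#' @param sor_omega Over-relaxation factor for the pressure solve.
#' @param n_channels Number of odorant dye channels `K` (default 3).
#' @param obstacles List of internal boundaries from [obstacle()].
#' @return A `flow_grid` object.
#' @export
flow_grid <- function(nx = 140, ny = 140, cell_size = 0.02, dt = 0.030,
                      viscosity = 1e-5, dye_diffusion = 1e-5,
                      evaporation_rate = 0.02, solver_iters = 20,
                      sor_omega = 1.7, n_channels = 3, obstacles = list()) {
  stopifnot(nx >= 4, ny >= 4, cell_size > 0, dt > 0, viscosity >= 0,
            dye_diffusion >= 0, evaporation_rate >= 0, solver_iters >= 1,
            n_channels >= 1)
  mask <- matrix(1L, nx, ny)
  mask[c(1, nx), ] <- 0L
  mask[, c(1, ny)] <- 0L
  for (ob in obstacles) {
    stopifnot(inherits(ob, "pb_obstacle"))
    if (ob$x0 < 1 || ob$x1 > nx || ob$y0 < 1 || ob$y1 > ny)
      stop("obstacle lies outside the grid", call. = FALSE)
    mask[ob$x0:ob$x1, ob$y0:ob$y1] <- 0L
  }
  structure(list(
    nx = nx, ny = ny, cell_size = cell_size, dt = dt,
    viscosity = viscosity, dye_diffusion = dye_diffusion,
    evaporation_rate = evaporation_rate, solver_iters = solver_iters,
    sor_omega = sor_omega, n_channels = n_channels,
    u = matrix(0, nx, ny), v = matrix(0, nx, ny),
    dye = replicate(n_channels, matrix(0, nx, ny), simplify = FALSE),
    mask = mask, obstacles = obstacles
  ), class = "flow_grid")
}

#' @export
print.flow_grid <- function(x, ...) {
  cat(sprintf(
    "<flow_grid> %d x %d cells (%.3g m/cell), %d dye channel(s), dt = %g s\n",
    x$nx, x$ny, x$cell_size, x$n_channels, x$dt))
  cat(sprintf("  max |velocity| %.4g m/s, total dye mass %.4g\n",
              max(abs(c(x$u, x$v))), sum(vapply(x$dye, sum, numeric(1)))))
  invisible(x)
}

#' Define an internal boundary (axis-aligned solid rectangle)
#'
#' @param x0,x1,y0,y1 Inclusive 1-based cell index ranges of the solid block.
#' @return A `pb_obstacle` used by [flow_grid()] and [proximity()].
#' @export
obstacle <- function(x0, x1, y0, y1) {
  stopifnot(x0 <= x1, y0 <= y1)
  structure(list(x0 = as.integer(x0), x1 = as.integer(x1),
                 y0 = as.integer(y0), y1 = as.integer(y1)),
            class = "pb_obstacle")
}

#' Define a wind (convection) source
#'
#' A wind source adds a fixed vector to the velocity field in a set of cells
#' on every step, the standard way a fan or vent is represented in an
#' interactive fluid solver.
#'
#' @param cells Two-column matrix (or data frame) of 1-based cell indices.
#' @param force Length-2 velocity increment (m/s added per step).
#' @param strength Runtime-adjustable scale applied to `force`.
#' @return A `wind_source` object.
#' @export
wind_source <- function(cells, force, strength = 1) {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  stopifnot(ncol(cells) == 2, length(force) == 2)
  structure(list(cells = cells, force = as.numeric(force),
                 strength = strength), class = "wind_source")
}

#' Define an odorant plume source
#'
#' Dye is injected at `rate * dt` concentration units per CFD step into one
#' cell of one odorant channel.
#'
#' @param cell Length-2 vector of 1-based cell indices.
#' @param channel Odorant channel index (1-based, `<= n_channels`).
#' @param rate Emission rate (dye units per second), `>= 0`.
#' @return A `plume_source` object.
#' @export
plume_source <- function(cell, channel = 1, rate = 50) {
  stopifnot(length(cell) == 2, rate >= 0, channel >= 1)
  structure(list(cell = as.integer(cell), channel = as.integer(channel),
                 rate = rate), class = "plume_source")
}

check_cells_inside <- function(cells, grid, what) {
  bad <- cells[, 1] < 1 | cells[, 1] > grid$nx |
    cells[, 2] < 1 | cells[, 2] > grid$ny
  if (any(bad))
    stop(sprintf("%s lies outside the %d x %d grid", what, grid$nx, grid$ny),
         call. = FALSE)
}

#' Advance the fluid one time step
#'
#' Runs one step of the stable-fluids pipeline: velocity gains the wind and
#' body forces, diffuses, is projected to be divergence-free, self-advects
#' and is projected again; each dye channel gains its sources, diffuses,
#' advects along the velocity field, evaporates and is clamped at zero.
#' Velocity respects no-through-flow at walls and obstacles; dye is
#' zero-flux at all walls.
#'
#' @param grid A [flow_grid()].
#' @param winds List of [wind_source()] objects.
#' @param sources List of [plume_source()] objects.
#' @param body_forces Data frame with columns `i`, `j`, `fx`, `fy` of extra
#'   per-cell velocity increments (e.g. from
#'   [robot_perturbation_forces()]), or `NULL`.
#' @return The advanced `flow_grid`.
#' @export
step_fluid <- function(grid, winds = list(), sources = list(),
                       body_forces = NULL) {
  stopifnot(inherits(grid, "flow_grid"))
  fi <- integer(0); fx <- numeric(0); fy <- numeric(0)
  for (w in winds) {
    stopifnot(inherits(w, "wind_source"))
    check_cells_inside(w$cells, grid, "wind source")
    idx <- (w$cells[, 1] - 1L) + (w$cells[, 2] - 1L) * grid$nx
    fi <- c(fi, idx)
    fx <- c(fx, rep(w$force[1] * w$strength, nrow(w$cells)))
    fy <- c(fy, rep(w$force[2] * w$strength, nrow(w$cells)))
  }
  if (!is.null(body_forces) && length(body_forces$i) > 0) {
    check_cells_inside(cbind(body_forces$i, body_forces$j), grid, "body force")
    fi <- c(fi, (body_forces$i - 1L) + (body_forces$j - 1L) * grid$nx)
    fx <- c(fx, body_forces$fx)
    fy <- c(fy, body_forces$fy)
  }
  si <- integer(0); sc <- integer(0); sr <- numeric(0)
  for (s in sources) {
    stopifnot(inherits(s, "plume_source"))
    check_cells_inside(matrix(s$cell, 1), grid, "plume source")
    if (s$channel > grid$n_channels)
      stop("plume source channel exceeds grid n_channels", call. = FALSE)
    si <- c(si, (s$cell[1] - 1L) + (s$cell[2] - 1L) * grid$nx)
    sc <- c(sc, s$channel - 1L)
    sr <- c(sr, s$rate)
  }
  u <- grid$u + 0; v <- grid$v + 0
  dye <- lapply(grid$dye, function(d) d + 0)
  ok <- cpp_fluid_step(u, v, dye, grid$mask, grid$nx, grid$ny,
                       grid$dt, grid$cell_size, grid$viscosity,
                       grid$dye_diffusion, grid$evaporation_rate,
                       grid$solver_iters, grid$sor_omega,
                       as.integer(fi), fx, fy,
                       as.integer(si), as.integer(sc), sr)
  if (!ok)
    stop("non-finite field values after fluid step (numerical-state error)",
         call. = FALSE)
  grid$u <- u; grid$v <- v; grid$dye <- dye
  grid
}

#' Sample per-channel odorant concentration at a world position
#'
#' Bilinear interpolation of the four cells surrounding the sensor location.
#' A position exactly at a cell center returns that cell's dye values.
#'
#' @param grid A [flow_grid()].
#' @param position Length-2 position in metres.
#' @param normalize Optional vector of per-channel maxima (e.g. the dye value
#'   at each source cell) to divide by, for logging on the 0-1 scale;
#'   `NULL` for raw concentrations.
#' @return Numeric vector of `n_channels` concentrations.
#' @export
sample_concentrations <- function(grid, position, normalize = NULL) {
  stopifnot(inherits(grid, "flow_grid"), length(position) == 2)
  h <- grid$cell_size
  if (position[1] < 0 || position[1] > grid$nx * h ||
      position[2] < 0 || position[2] > grid$ny * h)
    stop("sample position outside the grid", call. = FALSE)
  x <- position[1] / h
  y <- position[2] / h
  out <- vapply(grid$dye, function(d)
    cpp_bilinear_sample(d, grid$nx, grid$ny, x, y), numeric(1))
  if (!is.null(normalize)) {
    stopifnot(length(normalize) == grid$n_channels)
    out <- out / ifelse(normalize > 0, normalize, 1)
  }
  out
}

#' Forces exerted on the flow by the robot's leading edge
#'
#' The robot perturbs the plume by injecting forces along the leading edge of
#' its chassis: at every CFD cell the edge crosses, a force equal and
#' opposite to the flow vector currently stored in that cell is added,
#' scaled by `magnitude` (the robot's adjustable effect on the flow field).
#' The edge is discretized by supersampling at one sample per cell width and
#' de-duplicating cells.
#'
#' @param grid A [flow_grid()].
#' @param robot A [robot_state()] whose footprint lies inside the grid.
#' @param magnitude Scale of the robot's effect on the flow (default 1).
#' @return Tibble with columns `i`, `j`, `fx`, `fy`, one row per edge cell;
#'   feed to [step_fluid()] as `body_forces`.
#' @export
robot_perturbation_forces <- function(grid, robot, magnitude = 1) {
  stopifnot(inherits(grid, "flow_grid"), inherits(robot, "robot_state"))
  tibble::as_tibble(perturbation_forces_fast(grid, robot, magnitude))
}

# internal fast path (plain list, no tibble construction) used per trial step
perturbation_forces_fast <- function(grid, robot, magnitude = 1) {
  h <- grid$cell_size
  dir <- c(cos(robot$heading), sin(robot$heading))
  perp <- c(-dir[2], dir[1])
  front <- robot$position + dir * robot$length / 2
  a <- front + perp * robot$width / 2
  b <- front - perp * robot$width / 2
  n <- max(2L, ceiling(robot$width / h) + 1L)
  tt <- seq.int(0, 1, length.out = n)
  px <- a[1] + (b[1] - a[1]) * tt
  py <- a[2] + (b[2] - a[2]) * tt
  i <- floor(px / h) + 1L
  j <- floor(py / h) + 1L
  if (any(i < 1L) || any(i > grid$nx) || any(j < 1L) || any(j > grid$ny))
    stop("robot leading edge outside the grid", call. = FALSE)
  keep <- !duplicated(i * 100000L + j)
  i <- i[keep]; j <- j[keep]
  idx <- cbind(i, j)
  list(i = as.integer(i), j = as.integer(j),
       fx = -magnitude * grid$u[idx],
       fy = -magnitude * grid$v[idx])
}

#' Total dye mass over fluid cells
#'
#' @param grid A [flow_grid()].
#' @param channel Channel index, or `NULL` for all channels summed.
#' @return Total concentration summed over fluid cells.
#' @export
total_dye_mass <- function(grid, channel = NULL) {
  chans <- if (is.null(channel)) seq_len(grid$n_channels) else channel
  sum(vapply(chans, function(k) sum(grid$dye[[k]][grid$mask == 1L]),
             numeric(1)))
}

#' Discrete divergence of the velocity field
#'
#' Net face outflow per cell divided by the cell size — the quantity driven
#' to zero by the projection sub-step — over all interior (fluid) cells.
#' Solid cells are `NA`.
#'
#' @param grid A [flow_grid()].
#' @return Matrix of `div(u, v)` values (1/s).
#' @export
flow_divergence <- function(grid) {
  nx <- grid$nx; ny <- grid$ny; h <- grid$cell_size
  out <- matrix(NA_real_, nx, ny)
  i <- 2:(nx - 1); j <- 2:(ny - 1)
  dv <- (grid$u[i, j] - grid$u[i - 1, j] +
           grid$v[i, j] - grid$v[i, j - 1]) / h
  dv[grid$mask[i, j] != 1L] <- NA_real_
  out[i, j] <- dv
  out
}
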