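#' Tidy a trial result
#'
#' @param x A [run_trial()] result.
#' @param what `"trajectory"` (default) or `"concentrations"`.
#' @param ... Unused.
#' @return A tibble with one row per CFD step.
#' @export
tidy.trial_result <- function(x, what = c("trajectory", "concentrations"),
                              ...) {
  what <- match.arg(what)
  out <- x[[what]]
  if (is.null(out))
    stop("trial was run with log = FALSE", call. = FALSE)
  out
}

#' Summarize a trial result in one row
#'
#' @param x A [run_trial()] result.
#' @param ... Unused.
#' @return One-row tibble: `reached`, `time_to_source`, `final_distance`,
#'   `collisions`, `n_cfd_steps`, `n_neural_steps`, `beta_cycles`.
#' @export
glance.trial_result <- function(x, ...) {
  tibble::tibble(
    reached = x$reached,
    time_to_source = x$time_to_source,
    final_distance = x$final_distance,
    collisions = x$collisions,
    n_cfd_steps = x$n_cfd_steps,
    n_neural_steps = x$n_neural_steps,
    beta_cycles = beta_cycles(x$n_neural_steps,
                              x$n_neural_steps / max(1, x$n_cfd_steps))
  )
}

#' Plot a trial
#'
#' `what = "trajectory"` draws the robot path; `what = "concentrations"`
#' draws the per-channel odor concentration experienced at the sensor over
#' time (one point per CFD step).
#'
#' @param object A [run_trial()] result.
#' @param what `"trajectory"` or `"concentrations"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trial_result <- function(object,
                                  what = c("trajectory", "concentrations"),
                                  ...) {
  what <- match.arg(what)
  if (what == "trajectory") {
    tr <- tidy(object, "trajectory")
    ggplot2::ggplot(tr, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$t)) +
      ggplot2::geom_path() +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "x (m)", y = "y (m)", colour = "t (s)",
                    title = "Robot trajectory")
  } else {
    cc <- tidy(object, "concentrations")
    long <- tidyr_pivot(cc)
    ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                       colour = .data$channel)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "t (s)", y = "concentration (a.u.)",
                    colour = "channel",
                    title = "Odor concentrations at the sensor")
  }
}

# minimal long-format pivot (avoids a hard tidyr dependency)
tidyr_pivot <- function(cc) {
  chans <- setdiff(names(cc), "t")
  dplyr::bind_rows(lapply(chans, function(ch)
    tibble::tibble(t = cc$t, channel = ch, value = cc[[ch]])))
}

#' Tidy an evolution history
#'
#' @param x A [run_evolution()] result.
#' @param ... Unused.
#' @return Tibble with one row per (generation, individual): `generation`,
#'   `individual`, `fitness`, `seed`.
#' @export
tidy.evolution_history <- function(x, ...) x$history

#' Summarize an evolution run in one row
#'
#' @param x A [run_evolution()] result.
#' @param ... Unused.
#' @return One-row tibble: generations, population, best fitness overall,
#'   best of the final generation, and the initial generation's median
#'   fitness.
#' @export
glance.evolution_history <- function(x, ...) {
  h <- x$history
  g0 <- h$fitness[h$generation == min(h$generation)]
  gl <- h$fitness[h$generation == max(h$generation)]
  tibble::tibble(
    generations = max(h$generation),
    population = x$config$population,
    best_fitness = min(h$fitness),
    final_best = min(gl),
    gen0_median = median(g0)
  )
}

#' Plot fitness across generations
#'
#' Per-individual fitnesses as points with the best-so-far envelope.
#'
#' @param object A [run_evolution()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evolution_history <- function(object, ...) {
  h <- object$history
  best <- h |>
    dplyr::group_by(.data$generation) |>
    dplyr::summarise(best = min(.data$fitness), .groups = "drop") |>
    dplyr::mutate(best_so_far = cummin(.data$best))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$generation,
                                  y = .data$fitness)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_step(data = best,
                       ggplot2::aes(y = .data$best_so_far),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "generation", y = "fitness (s; lower is better)",
                  title = "Evolution of time-to-source fitness")
}
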