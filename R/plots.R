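# ggplot2 figures for the three result types. autoplot() returns the plot
# object; callers theme/save as they wish.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Time-course plot of a trajectory
#'
#' One line per compartment (S, E, D, I) against time, mirroring the
#' published time-course figures.
#'
#' @param object A `trajectory` from [simulate_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' p <- model_params(eta = 4, beta = 0.5, gamma = 0.05, mu = 0.05,
#'                   alpha = 0.01, sigma = 0.049, n_total = 100)
#' autoplot(simulate_model(p, "sedi", t_end = 1000))
#' @method autoplot trajectory
#' @export
autoplot.trajectory <- function(object, ...) {
  dat <- tidy(object)
  if (trajectory_model(object) == "sei") {
    dat <- dplyr::filter(dat, .data$compartment != "D")
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data$count,
                                    colour = .data$compartment)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "time (days)", y = "count", colour = NULL,
                  title = sprintf("%s model time-course",
                                  toupper(trajectory_model(object)))) +
    ggplot2::theme_minimal()
}

#' Two-dimensional phase portrait of a trajectory
#'
#' Projects the trajectory onto a pair of compartments (default S vs I),
#' with the start marked; equilibria of the model can be overlaid by the
#' caller.
#'
#' @param trajectory A `trajectory`.
#' @param x,y Compartment names among `"S"`, `"E"`, `"D"`, `"I"`.
#' @return A ggplot object.
#' @examples
#' p <- model_params(eta = 4, beta = 0.5, gamma = 0.05, mu = 0.05,
#'                   alpha = 0.01, n_total = 100)
#' plot_phase_portrait(simulate_model(p, "sei", t_end = 1000), "S", "I")
#' @export
plot_phase_portrait <- function(trajectory, x = "S", y = "I") {
  stopifnot(inherits(trajectory, "trajectory"),
            x %in% c("S", "E", "D", "I"), y %in% c("S", "E", "D", "I"))
  dat <- tibble::as_tibble(trajectory)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::geom_path(linewidth = 0.6) +
    ggplot2::geom_point(data = dat[1, ], colour = "red", size = 2) +
    ggplot2::labs(x = x, y = y, title = "phase portrait") +
    ggplot2::theme_minimal()
}

#' Tile plot of a phase diagram
#'
#' Analytic endemic/free regions over the (R0, p) grid with the threshold
#' curve `p = 1 - 1/R0` overlaid; simulated-layer disagreements, if any,
#' are marked.
#'
#' @param object A [phase_diagram()].
#' @param layer `"analytic"` or `"simulated"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(phase_diagram(resolution = 5, simulate = FALSE))
#' @method autoplot phase_diagram
#' @export
autoplot.phase_diagram <- function(object, layer = c("analytic", "simulated"),
                                   ...) {
  layer <- match.arg(layer)
  col <- paste0("outcome_", layer)
  dat <- tibble::as_tibble(object)
  curve <- tibble::tibble(r0 = seq(max(min(dat$r0), 1.01), max(dat$r0),
                                   length.out = 200))
  curve$p <- 1 - 1 / curve$r0
  gg <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$r0, y = .data$p)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data[[col]])) +
    ggplot2::geom_line(data = curve, linetype = "dashed") +
    ggplot2::labs(x = expression(R[0]), y = "defended fraction p",
                  fill = NULL,
                  title = sprintf("%s outcome; dashed: p = 1 - 1/R0", layer)) +
    ggplot2::theme_minimal()
  if (layer == "simulated" && !all(is.na(dat$outcome_simulated))) {
    mism <- dat[!is.na(dat$outcome_simulated) &
                  dat$outcome_simulated != dat$outcome_analytic, ]
    if (nrow(mism) > 0) {
      gg <- gg + ggplot2::geom_point(data = mism, shape = 4, size = 2)
    }
  }
  gg
}
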