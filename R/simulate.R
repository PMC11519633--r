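# Deterministic time integration with deSolve. lsodar supplies both the
# adaptive (stiffness-switching) stepper and root-finding, used here to stop
# integration once the right-hand side has decayed to an equilibrium.

#' Integrate a model forward in time
#'
#' Solves the SEI or SEDI system with an adaptive, stiffness-switching
#' solver (`deSolve::lsodar`). Integration stops early when the infinity
#' norm of the right-hand side falls below `equilibrium_tol * n_total`
#' per day (termination reason `"converged"`), otherwise it runs to
#' `t_end` (`"horizon_reached"`).
#'
#' The default initial state is the standard invasion setup: all `N`
#' plants susceptible and a single founding insect (`S0 = N`, `E0 = 0`,
#' `D0 = 0`, `I0 = 1`). Initial states are required to satisfy
#' `s + e + d = n_total`; set `check_conservation = FALSE` to start off
#' the manifold (the flows then relax the plant total back towards `N`).
#' Tiny negative solver undershoots are clipped to zero in the returned
#' table only; raw solver output is kept internally so the audit in
#' [conservation_error()] sees the integrator's own numbers.
#'
#' @param params A [model_params()].
#' @param model `"sei"` or `"sedi"`. For `"sei"`, `sigma` must be 0 and the
#'   defended column is identically 0.
#' @param initial A [system_state()] or named vector; `NULL` for the
#'   default invasion state.
#' @param t_end Horizon in days. The default 5000 d covers the slowest
#'   timescale of interest (a 0.001/day rate has a 1000-day scale).
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param equilibrium_tol Early-termination threshold on the RHS infinity
#'   norm, in units of `n_total` per day. `NULL` disables early stopping.
#' @param n_out Minimum number of recorded output points.
#' @param check_conservation Enforce `s + e + d = n_total` at `t = 0`.
#' @return A `trajectory` tibble with columns `t`, `S`, `E`, `D`, `I` and
#'   attributes `model`, `params`, `solver` (tolerances and termination
#'   reason). Has [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()] methods.
#' @examples
#' p <- model_params(eta = 4, beta = 0.5, gamma = 0.05, mu = 0.05,
#'                   alpha = 0.01, sigma = 0.049, n_total = 100)
#' traj <- simulate_model(p, "sedi", t_end = 2000)
#' glance(traj)
#' @export
simulate_model <- function(params, model = c("sedi", "sei"), initial = NULL,
                           t_end = 5000, rtol = 1e-8, atol = 1e-10,
                           equilibrium_tol = 1e-9, n_out = 201,
                           check_conservation = TRUE) {
  model <- match.arg(model)
  params <- as_model_params(params)
  if (model == "sei" && params$sigma != 0) {
    stop("SEI model requires sigma = 0", call. = FALSE)
  }
  if (is.null(initial)) {
    initial <- system_state(s = params$n_total, i = 1)
  }
  initial <- as_system_state(initial)
  if (t_end <= 0) stop("`t_end` must be positive", call. = FALSE)
  n <- params$n_total
  plant_total <- initial[["s"]] + initial[["e"]] + initial[["d"]]
  if (check_conservation && abs(plant_total - n) > 1e-6 * n) {
    stop("initial state violates s + e + d = n_total (",
         format(plant_total), " vs ", format(n),
         "); fix the state or pass check_conservation = FALSE", call. = FALSE)
  }

  y0 <- c(S = initial[["s"]], E = initial[["e"]],
          D = initial[["d"]], I = initial[["i"]])
  deriv <- function(t, y, parms) {
    list(rhs_core(model, y[["S"]], y[["E"]], y[["D"]], y[["I"]], params))
  }
  rootfun <- NULL
  if (!is.null(equilibrium_tol)) {
    rootfun <- function(t, y, parms) {
      rhs <- rhs_core(model, y[["S"]], y[["E"]], y[["D"]], y[["I"]], params)
      max(abs(rhs)) - equilibrium_tol * n
    }
  }
  times <- seq(0, t_end, length.out = max(2L, n_out))
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsodar", rtol = rtol, atol = atol,
                      rootfunc = rootfun)
  sol <- as.data.frame(unclass(sol))
  terminated_early <- nrow(sol) > 0 && max(sol$time) < t_end - 1e-9
  k <- nrow(sol)
  final_rhs <- rhs_core(model, sol$S[k], sol$E[k], sol$D[k], sol$I[k], params)
  converged <- !is.null(equilibrium_tol) &&
    (terminated_early || max(abs(final_rhs)) < equilibrium_tol * n)

  out <- tibble::tibble(
    t = sol$time,
    S = pmax(sol$S, 0), E = pmax(sol$E, 0),
    D = pmax(sol$D, 0), I = pmax(sol$I, 0)
  )
  attr(out, "raw") <- sol
  attr(out, "model") <- model
  attr(out, "params") <- params
  attr(out, "solver") <- list(
    method = "lsodar", rtol = rtol, atol = atol,
    equilibrium_tol = equilibrium_tol,
    termination = if (converged) "converged" else "horizon_reached")
  class(out) <- c("trajectory", class(out))
  out
}

trajectory_params <- function(traj) attr(traj, "params")
trajectory_model <- function(traj) attr(traj, "model")

#' Final state of a trajectory if it has reached equilibrium
#'
#' Evaluates the model right-hand side at the last recorded state and
#' returns that state when its infinity norm is below `tol * n_total` per
#' day, `NULL` otherwise.
#'
#' @param trajectory A `trajectory` from [simulate_model()].
#' @param tol Norm threshold in units of `n_total` per day.
#' @return A [system_state()] or `NULL`.
#' @examples
#' p <- model_params(eta = 0.05, beta = 0.5, gamma = 0.05, mu = 0.05,
#'                   alpha = 0.01, n_total = 100)
#' detect_equilibrium(simulate_model(p, "sei"))
#' @export
detect_equilibrium <- function(trajectory, tol = 1e-9) {
  stopifnot(inherits(trajectory, "trajectory"), nrow(trajectory) > 0)
  params <- trajectory_params(trajectory)
  last <- trajectory[nrow(trajectory), ]
  state <- system_state(s = last$S, e = last$E, d = last$D, i = last$I,
                        t = last$t)
  rhs <- model_rhs(trajectory_model(trajectory), state, params)
  if (max(abs(rhs)) < tol * params$n_total) state else NULL
}

#' Maximum deviation of the total plant population along a trajectory
#'
#' The continuous systems conserve the plant total exactly
#' (`dN/dt = 0`); this audits how well the numerical solution honors
#' it. Uses the raw (unclipped) solver output.
#'
#' @param trajectory A `trajectory` from [simulate_model()].
#' @return Max over recorded times of `|S + E + D - n_total|`, in plants.
#' @examples
#' p <- model_params(eta = 4, beta = 0.5, gamma = 0.05, mu = 0.05,
#'                   alpha = 0.01, n_total = 100)
#' conservation_error(simulate_model(p, "sei", t_end = 100))
#' @export
conservation_error <- function(trajectory) {
  stopifnot(inherits(trajectory, "trajectory"), nrow(trajectory) > 0)
  raw <- attr(trajectory, "raw")
  n <- trajectory_params(trajectory)$n_total
  max(abs(raw$S + raw$E + raw$D - n))
}

#' @export
print.trajectory <- function(x, ...) {
  solver <- attr(x, "solver")
  cat(sprintf("<trajectory> %s model, %d points over %g days (%s)\n",
              toupper(trajectory_model(x)), nrow(x), max(x$t),
              solver$termination))
  NextMethod()
}
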