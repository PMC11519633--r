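#' Right-hand side of the SEI model
#'
#' Instantaneous rates of the susceptible-exploited-insect system:
#' \deqn{dS/dt = \mu N - \eta I S/N - \mu S + \alpha E}
#' \deqn{dE/dt = \eta I S/N - (\mu + \alpha) E}
#' \deqn{dI/dt = \beta \eta I S/N - \gamma I}
#' Germinating plants (rate `mu * N`) all enter the susceptible pool;
#' `S/N` is the prevalence of susceptibility seen by an ovipositing insect.
#' On the conservation manifold `S + E = N` the plant rates cancel exactly,
#' so the total plant population is constant (`dN/dt = 0`).
#'
#' @param state A [system_state()] (or named list/vector with `s`, `e`, `i`);
#'   the defended compartment must be 0 for this model.
#' @param params A [model_params()] with `sigma = 0`.
#' @return Named numeric vector `c(ds, de, di)` of rates per day.
#' @examples
#' p <- model_params(eta = 4, beta = 0.5, gamma = 1 / 20,
#'                   mu = 0.05, alpha = 0.01, n_total = 100)
#' sei_rhs(system_state(s = 50, e = 50, i = 10), p)
#' @export
sei_rhs <- function(state, params) {
  params <- as_model_params(params)
  state <- as_system_state(state)
  if (params$sigma != 0) {
    stop("SEI model requires `sigma = 0`; use sedi_rhs() for defended plants",
         call. = FALSE)
  }
  if (state[["d"]] != 0) {
    stop("SEI state must have d = 0 (no defended compartment)", call. = FALSE)
  }
  with(params, {
    s <- state[["s"]]; e <- state[["e"]]; i <- state[["i"]]
    force_inf <- eta * i * s / n_total
    c(ds = mu * n_total - force_inf - mu * s + alpha * e,
      de = force_inf - (mu + alpha) * e,
      di = beta * force_inf - gamma * i)
  })
}

#' Right-hand side of the SEDI model
#'
#' Instantaneous rates of the susceptible-exploited-defended-insect system:
#' \deqn{dS/dt = (\mu - \sigma) N - \eta I S/N - \mu S + \alpha E}
#' \deqn{dE/dt = \eta I S/N - (\mu + \alpha) E}
#' \deqn{dD/dt = \sigma N - \mu D}
#' \deqn{dI/dt = \beta \eta I S/N - \gamma I}
#' A fraction `p = sigma/mu` of germinating plants carries constitutive
#' chemical defense and enters `D`, where generalist insects cannot
#' oviposit; the remainder enters `S`. At `sigma = 0` the system reduces to
#' [sei_rhs()]. Plant rates sum to zero on the manifold `S + E + D = N`.
#'
#' @param state A [system_state()] (or named list/vector).
#' @param params A [model_params()].
#' @return Named numeric vector `c(ds, de, dd, di)` of rates per day.
#' @examples
#' p <- model_params(eta = 4, beta = 0.5, gamma = 1 / 20,
#'                   mu = 0.05, alpha = 0.01, sigma = 0.049, n_total = 100)
#' sedi_rhs(system_state(s = 2, e = 0, d = 98, i = 0), p)  # Q*_Free: all zero
#' @export
sedi_rhs <- function(state, params) {
  params <- as_model_params(params)
  state <- as_system_state(state)
  with(params, {
    s <- state[["s"]]; e <- state[["e"]]; d <- state[["d"]]; i <- state[["i"]]
    force_inf <- eta * i * s / n_total
    c(ds = (mu - sigma) * n_total - force_inf - mu * s + alpha * e,
      de = force_inf - (mu + alpha) * e,
      dd = sigma * n_total - mu * d,
      di = beta * force_inf - gamma * i)
  })
}

# Unchecked rate computation shared by the public wrappers and the solver
# (the solver's internal Jacobian estimation perturbs every coordinate,
# including D, so this path must tolerate arbitrary finite states).
rhs_core <- function(model, s, e, d, i, params) {
  force_inf <- params$eta * i * s / params$n_total
  ds <- (params$mu - params$sigma) * params$n_total - force_inf -
    params$mu * s + params$alpha * e
  de <- force_inf - (params$mu + params$alpha) * e
  dd <- if (model == "sei") 0 else params$sigma * params$n_total - params$mu * d
  di <- params$beta * force_inf - params$gamma * i
  c(ds, de, dd, di)
}

model_rhs <- function(model, state, params) {
  model <- match.arg(model, c("sei", "sedi"))
  state <- as_system_state(state)
  rhs_core(model, state[["s"]], state[["e"]], state[["d"]], state[["i"]],
           params)
}

#' Does the insect population grow at the onset of attack?
#'
#' At a state with `I > 0`, the insect population grows iff
#' `S > N * gamma / (eta * beta)`, equivalently `R0 > N / S`. With full
#' susceptibility (`S = N`) this is the classic invasion condition
#' `R0 > 1`. The sign of the insect rate returned by the model right-hand
#' side agrees with this algebraic rearrangement by construction.
#'
#' @param state A [system_state()] with `i > 0`.
#' @inheritParams sedi_rhs
#' @return `TRUE` iff `dI/dt > 0` at the state.
#' @examples
#' p <- model_params(eta = 4, beta = 0.5, gamma = 1 / 20, n_total = 100)
#' insect_growth_at_onset(system_state(s = 3, i = 1), p)  # 3 > 2.5
#' @export
insect_growth_at_onset <- function(state, params) {
  params <- as_model_params(params)
  state <- as_system_state(state)
  if (state[["i"]] <= 0) {
    stop("the growth condition is vacuous at I = 0: it is derived for I != 0",
         call. = FALSE)
  }
  state[["s"]] > params$n_total * params$gamma / (params$eta * params$beta)
}
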