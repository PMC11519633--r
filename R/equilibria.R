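# Closed-form fixed points of both models. Each constructor returns a one-row
# tibble so that several equilibria row-bind into the CSV-exportable table the
# package documents (label, S, E, D, I, exists, R0, p, p_critical).

new_equilibrium <- function(label, s, e, d, i, exists, params) {
  r0 <- reproduction_number(params)
  p <- defended_fraction(params)
  out <- tibble::tibble(
    label = label,
    s_star = s, e_star = e, d_star = d, i_star = i,
    exists = exists,
    r0 = r0, p = p,
    p_critical = if (r0 > 0) critical_threshold(r0) else NA_real_
  )
  attr(out, "params") <- params
  class(out) <- c("equilibrium", class(out))
  out
}

# strict inequality with an absolute guard band so floating-point noise at
# the boundary cannot flip the existence flag back and forth
EXISTS_TOL <- 1e-12

#' Insect-free equilibrium of the SEI model
#'
#' The oviposition- and insect-free fixed point `H*_Free = (N, 0, 0)`:
#' every plant is susceptible and no insects are present. It always exists;
#' it is asymptotically stable iff `R0 < 1` and a saddle for `R0 > 1`
#' (see [stability_report()]).
#'
#' @param params A [model_params()] with `sigma = 0`.
#' @return A one-row `equilibrium` tibble (columns `label`, `s_star`,
#'   `e_star`, `d_star`, `i_star`, `exists`, `r0`, `p`, `p_critical`).
#' @examples
#' sei_free_equilibrium(model_params(eta = 4, beta = 0.5, gamma = 0.05))
#' @export
sei_free_equilibrium <- function(params) {
  params <- as_model_params(params)
  stopifnot("SEI model requires sigma = 0" = params$sigma == 0)
  new_equilibrium("sei_free", params$n_total, 0, 0, 0, TRUE, params)
}

#' Endemic equilibrium of the SEI model
#'
#' The fixed point with persisting insects,
#' \deqn{H^*_{Endemic} = (N/R_0,\; N(R_0-1)/R_0,\; N(\mu+\alpha)(R_0-1)/\eta),}
#' which exists (all components positive) iff `R0 > 1`. At `R0 = 1` it
#' degenerates onto the free equilibrium and is flagged `exists = FALSE`;
#' its coordinates are still reported for continuity plots.
#'
#' @inheritParams sei_free_equilibrium
#' @return A one-row `equilibrium` tibble.
#' @examples
#' p <- model_params(eta = 4, beta = 0.5, gamma = 1 / 20,
#'                   mu = 0.05, alpha = 0.01, n_total = 100)
#' sei_endemic_equilibrium(p)  # (2.5, 97.5, 58.5) at R0 = 40
#' @export
sei_endemic_equilibrium <- function(params) {
  params <- as_model_params(params)
  stopifnot("SEI model requires sigma = 0" = params$sigma == 0)
  r0 <- reproduction_number(params)
  if (r0 <= 0) stop("endemic equilibrium requires R0 > 0", call. = FALSE)
  n <- params$n_total
  new_equilibrium("sei_endemic",
                  s = n / r0,
                  e = n * (r0 - 1) / r0,
                  d = 0,
                  i = n * (params$mu + params$alpha) * (r0 - 1) / params$eta,
                  exists = (r0 - 1) > EXISTS_TOL,
                  params)
}

#' Insect-free equilibrium of the SEDI model
#'
#' With a fraction `p = sigma/mu` of germination defended, the insect-free
#' fixed point is `Q*_Free = ((1-p)N, 0, 0)` in the reduced (S, E, I)
#' coordinates, with the defended compartment at its steady state
#' `D* = pN` (from `sigma N - mu D = 0`). Always exists; stable iff
#' `R0 < 1` or `p > 1 - 1/R0`.
#'
#' @param params A [model_params()].
#' @return A one-row `equilibrium` tibble.
#' @examples
#' p <- model_params(eta = 4, beta = 0.5, gamma = 0.05,
#'                   mu = 0.05, sigma = 0.049, n_total = 100)
#' sedi_free_equilibrium(p)  # S* = 2, D* = 98
#' @export
sedi_free_equilibrium <- function(params) {
  params <- as_model_params(params)
  p <- defended_fraction(params)
  n <- params$n_total
  new_equilibrium("sedi_free", (1 - p) * n, 0, p * n, 0, TRUE, params)
}

#' Endemic equilibrium of the SEDI model
#'
#' \deqn{Q^*_{Endemic} = \left(\frac{N}{R_0},\;
#'   \left(1 - p - \frac{1}{R_0}\right) N,\;
#'   \left(1 - p - \frac{1}{R_0}\right) \frac{(\mu+\alpha) N R_0}{\eta}\right)}
#' with `D* = pN`. The exploited-plant and insect components share the sign
#' of `1 - p - 1/R0`, so the equilibrium exists iff `R0 > 1` and the
#' defended fraction is below the threshold `1 - 1/R0`. Above the threshold
#' the coordinates are reported with negative components and
#' `exists = FALSE`.
#'
#' @inheritParams sedi_free_equilibrium
#' @return A one-row `equilibrium` tibble.
#' @examples
#' p <- model_params(eta = 4, beta = 0.5, gamma = 0.05,
#'                   mu = 0.05, sigma = 0.04, alpha = 0.01, n_total = 100)
#' sedi_endemic_equilibrium(p)  # (2.5, 17.5, 10.5), exists
#' @export
sedi_endemic_equilibrium <- function(params) {
  params <- as_model_params(params)
  r0 <- reproduction_number(params)
  if (r0 <= 0) stop("endemic equilibrium requires R0 > 0", call. = FALSE)
  p <- defended_fraction(params)
  n <- params$n_total
  margin <- 1 - p - 1 / r0
  new_equilibrium("sedi_endemic",
                  s = n / r0,
                  e = margin * n,
                  d = p * n,
                  i = margin * (params$mu + params$alpha) * n * r0 / params$eta,
                  exists = (r0 - 1) > EXISTS_TOL && margin > EXISTS_TOL,
                  params)
}

#' Does an endemic equilibrium exist?
#'
#' For the SEI model: `R0 > 1`. For the SEDI model: `R0 > 1` and the
#' defended fraction `p` below the threshold `1 - 1/R0`. Agrees with the
#' `exists` flag of the corresponding endemic equilibrium.
#'
#' @inheritParams sedi_free_equilibrium
#' @param model `"sei"` or `"sedi"`.
#' @return Logical scalar.
#' @examples
#' p <- model_params(eta = 4, beta = 0.5, gamma = 0.05,
#'                   mu = 0.05, sigma = 0.049, n_total = 100)
#' endemic_exists(p, "sedi")  # FALSE: p = 0.98 > 0.975
#' @export
endemic_exists <- function(params, model = c("sei", "sedi")) {
  model <- match.arg(model)
  params <- as_model_params(params)
  r0 <- reproduction_number(params)
  if ((r0 - 1) <= EXISTS_TOL) return(FALSE)
  if (model == "sei") return(TRUE)
  (1 - defended_fraction(params) - 1 / r0) > EXISTS_TOL
}

#' All equilibria of a model as a table
#'
#' Row-binds the free and endemic equilibria of the chosen model into a
#' tidy table ready for CSV export.
#'
#' @inheritParams endemic_exists
#' @return An `equilibrium` tibble with two rows.
#' @examples
#' p <- model_params(eta = 4, beta = 0.5, gamma = 0.05,
#'                   mu = 0.05, alpha = 0.01, n_total = 100)
#' equilibria(p, "sei")
#' @export
equilibria <- function(params, model = c("sei", "sedi")) {
  model <- match.arg(model)
  params <- as_model_params(params)
  out <- if (model == "sei") {
    dplyr::bind_rows(sei_free_equilibrium(params),
                     sei_endemic_equilibrium(params))
  } else {
    dplyr::bind_rows(sedi_free_equilibrium(params),
                     sedi_endemic_equilibrium(params))
  }
  attr(out, "params") <- params
  class(out) <- c("equilibrium", class(out))
  out
}

equilibrium_state <- function(eq) {
  row <- eq[1, ]
  # negative diagnostics coordinates are meaningless as counts; clamp for
  # state construction only (callers needing raw coordinates read the tibble)
  system_state(s = max(row$s_star, 0), e = max(row$e_star, 0),
               d = max(row$d_star, 0), i = max(row$i_star, 0))
}
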