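# broom-style tidiers. tidy() returns one row per elementary quantity
# (eigenvalue, time point in long form, ...); glance() a one-row summary.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trajectory into long compartment-by-time form
#'
#' @param x A `trajectory` from [simulate_model()].
#' @param ... Unused.
#' @return A tibble with columns `t`, `compartment` (factor S, E, D, I) and
#'   `count`.
#' @method tidy trajectory
#' @export
tidy.trajectory <- function(x, ...) {
  out <- tidyr::pivot_longer(tibble::as_tibble(x), cols = c("S", "E", "D", "I"),
                             names_to = "compartment", values_to = "count")
  out$compartment <- factor(out$compartment, levels = c("S", "E", "D", "I"))
  out
}

#' One-row summary of a trajectory
#'
#' @param x A `trajectory`.
#' @param ... Unused.
#' @return A tibble with the model, final time and state, conservation
#'   error, termination reason and whether an equilibrium was reached
#'   (RHS norm below the solver's early-termination tolerance).
#' @method glance trajectory
#' @export
glance.trajectory <- function(x, ...) {
  solver <- attr(x, "solver")
  last <- x[nrow(x), ]
  tibble::tibble(
    model = trajectory_model(x),
    t_final = last$t,
    s_final = last$S, e_final = last$E, d_final = last$D, i_final = last$I,
    conservation_error = conservation_error(x),
    termination = solver$termination,
    at_equilibrium = !is.null(detect_equilibrium(x, tol = 1e-6))
  )
}

#' Eigenvalues of a stability report, one per row
#'
#' @param x A [stability_report()].
#' @param ... Unused.
#' @return A tibble with columns `eigenvalue` (complex), `real`,
#'   `imaginary`, suitable for CSV export.
#' @method tidy stability_report
#' @export
tidy.stability_report <- function(x, ...) {
  tibble::tibble(
    eigenvalue = x$eigenvalues,
    real = Re(x$eigenvalues),
    imaginary = Im(x$eigenvalues)
  )
}

#' One-row summary of a stability report
#'
#' @param x A [stability_report()].
#' @param ... Unused.
#' @return A tibble with the equilibrium label, classification, leading
#'   (largest) eigenvalue real part, the decoupled defended-direction
#'   eigenvalue, and the hyperbolicity tolerance.
#' @method glance stability_report
#' @export
glance.stability_report <- function(x, ...) {
  tibble::tibble(
    label = x$equilibrium$label,
    exists = x$equilibrium$exists,
    classification = x$classification,
    max_re = max(Re(x$eigenvalues)),
    d_eigenvalue = x$d_eigenvalue,
    tol = x$tol
  )
}

#' One-row summary of a phase diagram
#'
#' @param x A [phase_diagram()].
#' @param ... Unused.
#' @return A tibble with cell counts per analytic outcome, the number of
#'   boundary-band cells, and the off-boundary analytic/simulated
#'   agreement fraction.
#' @method glance phase_diagram
#' @export
glance.phase_diagram <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_endemic_analytic = sum(x$outcome_analytic == "endemic"),
    n_free_analytic = sum(x$outcome_analytic == "free"),
    n_near_boundary = sum(x$near_boundary),
    agreement = attr(x, "agreement")
  )
}
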