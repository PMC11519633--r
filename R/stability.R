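# Local stability of equilibria via the Jacobian of the reduced 3-D system.
# Both models are analyzed in (S, E, I) coordinates: the defended compartment
# decouples (dD/dt = sigma*N - mu*D involves no other variable), contributing
# an analytic eigenvalue -mu that is reported separately.

#' Jacobian of the reduced (S, E, I) system
#'
#' Matrix of partial derivatives of the reduced three-dimensional
#' right-hand side at a point. The constant germination inflows
#' (`mu*N` resp. `(mu-sigma)*N` and `sigma*N`) drop out under
#' differentiation, so the SEI and SEDI models share the same reduced
#' Jacobian:
#' \preformatted{
#'   [ -eta*I/N - mu        alpha        -eta*S/N        ]
#'   [  eta*I/N            -(mu+alpha)    eta*S/N        ]
#'   [  beta*eta*I/N        0             beta*eta*S/N - gamma ]
#' }
#'
#' @param params A [model_params()].
#' @param point A [system_state()] (or an `equilibrium` row) at which to
#'   evaluate; only `s` and `i` enter.
#' @param model `"sei"` or `"sedi"` (the reduced Jacobian is identical;
#'   the argument is kept for interface symmetry and validation).
#' @return A 3x3 numeric matrix with dimnames `c("s", "e", "i")`.
#' @examples
#' p <- model_params(eta = 4, beta = 0.5, gamma = 0.05, mu = 0.05,
#'                   alpha = 0.01, n_total = 100)
#' model_jacobian(p, system_state(s = 100))
#' @export
model_jacobian <- function(params, point, model = c("sei", "sedi")) {
  model <- match.arg(model)
  params <- as_model_params(params)
  if (inherits(point, "equilibrium")) {
    # raw coordinates, not clamped: diagnostics of non-existing equilibria
    # (negative components) linearize at the algebraic fixed point
    s <- point$s_star[1]; i <- point$i_star[1]
  } else {
    point <- as_system_state(point)
    s <- point[["s"]]; i <- point[["i"]]
  }
  with(params, {
    fi <- eta * i / n_total    # d(force)/dS
    fs <- eta * s / n_total    # d(force)/dI
    j <- matrix(c(
      -fi - mu,      alpha,        -fs,
       fi,          -(mu + alpha),  fs,
       beta * fi,    0,             beta * fs - gamma
    ), nrow = 3, byrow = TRUE)
    dimnames(j) <- list(c("s", "e", "i"), c("s", "e", "i"))
    j
  })
}

#' Sorted eigenvalues of a real 3x3 matrix
#'
#' Eigenvalues ordered by decreasing real part, ties broken by decreasing
#' imaginary part, so complex-conjugate pairs sit adjacently with the
#' positive-imaginary member first.
#'
#' @param m A 3x3 real matrix with finite entries.
#' @return A complex vector of length 3.
#' @examples
#' jacobian_eigenvalues(diag(c(-1, -2, -3)))
#' @export
jacobian_eigenvalues <- function(m) {
  if (!is.matrix(m) || any(dim(m) != 3L) || any(!is.finite(m))) {
    stop("`m` must be a 3x3 matrix with finite entries", call. = FALSE)
  }
  ev <- as.complex(eigen(m, only.values = TRUE)$values)
  ev[order(-Re(ev), -Im(ev))]
}

#' Classify an equilibrium from its eigenvalues
#'
#' Hyperbolicity-aware classification. An equilibrium with any eigenvalue
#' real part within `tol` of zero is `"nonhyperbolic"` (linearization is
#' inconclusive). Otherwise: all real parts negative gives a stable
#' equilibrium, all positive an unstable one, mixed signs a saddle; the
#' node/focus split is by the presence of an imaginary part exceeding
#' `tol` (damped or growing oscillation).
#'
#' @param eigenvalues A complex (or numeric) vector of eigenvalues.
#' @param tol Real-part tolerance for hyperbolicity, per day. The default
#'   `1e-9` sits well below the smallest rate constant of interest
#'   (0.001/day).
#' @return One of `"stable_node"`, `"stable_focus"`, `"saddle"`,
#'   `"unstable_node"`, `"unstable_focus"`, `"nonhyperbolic"`.
#' @examples
#' classify_eigenvalues(c(-1, -2, -3))
#' classify_eigenvalues(c(complex(real = -0.1, imaginary = 0.5),
#'                        complex(real = -0.1, imaginary = -0.5), -2))
#' @export
classify_eigenvalues <- function(eigenvalues, tol = 1e-9) {
  ev <- as.complex(eigenvalues)
  if (any(!is.finite(ev))) stop("eigenvalues must be finite", call. = FALSE)
  re <- Re(ev)
  if (any(abs(re) <= tol)) return("nonhyperbolic")
  oscillatory <- any(abs(Im(ev)) > tol)
  if (all(re < 0)) return(if (oscillatory) "stable_focus" else "stable_node")
  if (all(re > 0)) return(if (oscillatory) "unstable_focus" else "unstable_node")
  "saddle"
}

#' Stability report for an equilibrium
#'
#' Composes [model_jacobian()], [jacobian_eigenvalues()] and
#' [classify_eigenvalues()] at a computed equilibrium. The theory this
#' verifies numerically: the SEI free equilibrium is stable iff `R0 < 1`
#' and a saddle for `R0 > 1`; the SEDI free equilibrium is stable iff
#' `R0 < 1` or `p > 1 - 1/R0`; every existing endemic equilibrium is a
#' stable node or stable focus. A nonhyperbolic outcome is reported, never
#' raised as an error.
#'
#' @param params The [model_params()] the equilibrium was computed from.
#' @param equilibrium A one-row `equilibrium` tibble, e.g. from
#'   [sedi_free_equilibrium()].
#' @param model `"sei"` or `"sedi"`; defaults to the model encoded in the
#'   equilibrium label.
#' @param tol Hyperbolicity tolerance, see [classify_eigenvalues()].
#' @return A `stability_report` object: list with `equilibrium`,
#'   `eigenvalues` (reduced 3-D system), `d_eigenvalue` (`-mu`, the
#'   decoupled defended-compartment direction; `NA` for SEI),
#'   `classification`, and `tol`. Has [generics::tidy()] and
#'   [generics::glance()] methods.
#' @examples
#' p <- model_params(eta = 4, beta = 0.5, gamma = 0.05, mu = 0.05,
#'                   alpha = 0.01, n_total = 100)
#' stability_report(p, sei_endemic_equilibrium(p))
#' @export
stability_report <- function(params, equilibrium, model = NULL, tol = 1e-9) {
  params <- as_model_params(params)
  stopifnot(inherits(equilibrium, "equilibrium"), nrow(equilibrium) == 1L)
  if (is.null(model)) {
    model <- if (startsWith(equilibrium$label, "sedi")) "sedi" else "sei"
  }
  model <- match.arg(model, c("sei", "sedi"))
  j <- model_jacobian(params, equilibrium, model = model)
  ev <- jacobian_eigenvalues(j)
  structure(
    list(equilibrium = equilibrium,
         jacobian = j,
         eigenvalues = ev,
         d_eigenvalue = if (model == "sedi") -params$mu else NA_real_,
         classification = classify_eigenvalues(ev, tol = tol),
         model = model,
         tol = tol),
    class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  eq <- x$equilibrium
  cat(sprintf("<stability_report> %s: %s\n", eq$label, x$classification))
  cat(sprintf("  point (S, E, D, I) = (%g, %g, %g, %g)%s\n",
              eq$s_star, eq$e_star, eq$d_star, eq$i_star,
              if (eq$exists) "" else "  [does not exist]"))
  cat("  eigenvalues (per day):",
      paste(format(x$eigenvalues, digits = 4), collapse = ", "), "\n")
  if (!is.na(x$d_eigenvalue)) {
    cat(sprintf("  decoupled D-direction eigenvalue: %g\n", x$d_eigenvalue))
  }
  invisible(x)
}

is_stable <- function(report) {
  report$classification %in% c("stable_node", "stable_focus")
}
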