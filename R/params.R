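#' Model parameters for the SEI / SEDI plant-herbivore systems
#'
#' Bundles the rate constants and total plant population shared by the
#' susceptible-exploited-insect (SEI) model and its extension with
#' constitutively defended plants (SEDI). All rates are per day; populations
#' are dimensionless counts. Validation is eager: an invalid combination
#' fails here, so downstream simulation and equilibrium code never sees
#' inconsistent rates.
#'
#' @param eta Oviposition number: plants exploited per insect per day.
#' @param beta Deposition number: mean eggs laid per insect per exploited
#'   plant per day.
#' @param gamma Insect per-capita death rate per day; `1/gamma` is the mean
#'   insect lifespan in days. Must be strictly positive.
#' @param mu Plant per-capita germination-and-death rate per day. Equal
#'   germination and death rates keep the total plant population constant.
#' @param alpha Per-capita re-susceptibility rate of exploited plants per
#'   day (a plant can be oviposited several times in its life).
#' @param sigma Per-capita rate of germination with chemical defense per
#'   day. Zero recovers the SEI model; must satisfy `sigma <= mu`.
#' @param n_total Total plant count N (constant).
#'
#' @return An object of class `"model_params"`: a named list of the seven
#'   quantities above.
#'
#' @examples
#' p <- model_params(eta = 4, beta = 0.5, gamma = 1 / 20,
#'                   mu = 0.05, alpha = 0.01, sigma = 0.049, n_total = 100)
#' reproduction_number(p)
#' defended_fraction(p)
#' @export
model_params <- function(eta, beta, gamma, mu = 0, alpha = 0, sigma = 0,
                         n_total = 100) {
  vals <- list(eta = eta, beta = beta, gamma = gamma, mu = mu,
               alpha = alpha, sigma = sigma, n_total = n_total)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
    if (v < 0) stop("`", nm, "` must be nonnegative", call. = FALSE)
  }
  if (gamma <= 0) stop("`gamma` must be strictly positive", call. = FALSE)
  if (n_total <= 0) stop("`n_total` must be strictly positive", call. = FALSE)
  if (sigma > 0 && mu <= 0) {
    stop("`mu` must be positive when `sigma` > 0 (defended germination ",
         "requires germination)", call. = FALSE)
  }
  if (sigma > mu) {
    stop("`sigma` must not exceed `mu`: the defended germination rate is a ",
         "fraction of total germination", call. = FALSE)
  }
  structure(vals, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  eta = %g, beta = %g, gamma = %g (lifespan %g d)\n",
              x$eta, x$beta, x$gamma, 1 / x$gamma))
  cat(sprintf("  mu = %g, alpha = %g, sigma = %g, N = %g\n",
              x$mu, x$alpha, x$sigma, x$n_total))
  r0 <- reproduction_number(x)
  cat(sprintf("  R0 = %g, p = %g", r0, defended_fraction(x)))
  if (r0 > 0) cat(sprintf(", threshold 1 - 1/R0 = %g", critical_threshold(r0)))
  cat("\n")
  invisible(x)
}

as_model_params <- function(x) {
  if (inherits(x, "model_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    do.call(model_params, x[intersect(names(x),
      c("eta", "beta", "gamma", "mu", "alpha", "sigma", "n_total"))])
  } else {
    stop("cannot interpret `params`; use model_params()", call. = FALSE)
  }
}

#' System state of a compartment model at an instant
#'
#' A named numeric vector of compartment counts: susceptible plants `s`,
#' exploited plants `e`, defended plants `d` (identically 0 in the SEI
#' model) and insects `i`, plus the time `t` in days. States produced by
#' [simulate_model()] satisfy `s + e + d = n_total` up to solver tolerance;
#' states passed to the right-hand sides directly may sit off that manifold
#' (finite-difference Jacobian checks need this).
#'
#' @param s,e,d,i Nonnegative compartment counts.
#' @param t Time in days (default 0).
#' @return A named numeric vector of class `"system_state"`.
#' @examples
#' system_state(s = 99, i = 1)
#' @export
system_state <- function(s, e = 0, d = 0, i = 0, t = 0) {
  v <- c(s = s, e = e, d = d, i = i, t = t)
  if (any(!is.finite(v))) stop("state components must be finite", call. = FALSE)
  if (any(v[c("s", "e", "d", "i")] < 0)) {
    stop("compartment counts must be nonnegative", call. = FALSE)
  }
  structure(v, class = "system_state")
}

as_system_state <- function(x) {
  if (inherits(x, "system_state")) return(x)
  x <- unlist(as.list(x))
  nm <- names(x)
  if (is.null(nm)) stop("state must have named components", call. = FALSE)
  names(x) <- tolower(nm)
  system_state(s = x[["s"]],
               e = if ("e" %in% names(x)) x[["e"]] else 0,
               d = if ("d" %in% names(x)) x[["d"]] else 0,
               i = if ("i" %in% names(x)) x[["i"]] else 0,
               t = if ("t" %in% names(x)) x[["t"]] else 0)
}

#' Insect reproduction number
#'
#' The number of viable eggs an insect lays in its lifetime,
#' `R0 = eta * beta / gamma`: eggs per exploited plant per day, times plants
#' exploited per day, times the mean lifespan `1/gamma`. Endemic persistence
#' of the insect requires `R0 > 1`.
#'
#' @param params A [model_params()] object (or coercible list).
#' @return The dimensionless reproduction number.
#' @examples
#' reproduction_number(model_params(eta = 4, beta = 0.5, gamma = 1 / 20))
#' @export
reproduction_number <- function(params) {
  params <- as_model_params(params)
  params$eta * params$beta / params$gamma
}

#' Fraction of germinating plants that are defended
#'
#' `p = sigma / mu`, guaranteed in `[0, 1]` by the `sigma <= mu` invariant.
#' With no germination at all (`mu = 0`, forcing `sigma = 0`) the defended
#' inflow is empty and the fraction is 0 by convention.
#'
#' @inheritParams reproduction_number
#' @return The defended fraction p in `[0, 1]`.
#' @examples
#' defended_fraction(model_params(eta = 4, beta = 0.5, gamma = 0.05,
#'                                mu = 0.05, sigma = 0.049))
#' @export
defended_fraction <- function(params) {
  params <- as_model_params(params)
  if (params$mu == 0) return(0)
  params$sigma / params$mu
}

#' Critical defended fraction for insect eradication
#'
#' The herd-defense threshold `1 - 1/R0`: when the defended fraction p of
#' germinating plants exceeds it, the insect-free state is the only stable
#' equilibrium and a generalist insect with reproduction number `R0` cannot
#' remain endemic. Negative values (for `R0 < 1`) mean no defense is needed.
#'
#' @param r0 A positive reproduction number (vectorized).
#' @return `1 - 1/r0`, strictly increasing in `r0` and bounded above by 1.
#' @examples
#' critical_threshold(500)  # 0.998: >99.8% of germination must be defended
#' critical_threshold(1)    # 0: at R0 = 1 no defense is needed
#' @export
critical_threshold <- function(r0) {
  if (!is.numeric(r0) || any(!is.finite(r0)) || any(r0 <= 0)) {
    stop("`r0` must be positive and finite", call. = FALSE)
  }
  1 - 1 / r0
}

#' Read model parameters and initial conditions from a configuration file
#'
#' Reads a flat key-value YAML file with keys `eta, beta, gamma, mu, alpha,
#' sigma, n_total` and optionally `s0, e0, d0, i0, t_end`.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `params` ([model_params()]), `initial`
#'   ([system_state()] or `NULL` if no initial condition keys are present)
#'   and `t_end` (or `NULL`).
#' @examples
#' cfg <- read_params_config(
#'   system.file("extdata", "example-config.yaml", package = "plantdefense"))
#' cfg$params
#' @export
read_params_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a flat key-value mapping", call. = FALSE)
  names(raw) <- tolower(names(raw))
  pkeys <- intersect(names(raw),
                     c("eta", "beta", "gamma", "mu", "alpha", "sigma", "n_total"))
  params <- do.call(model_params, raw[pkeys])
  initial <- NULL
  if (any(c("s0", "e0", "d0", "i0") %in% names(raw))) {
    get0 <- function(k, default) if (k %in% names(raw)) raw[[k]] else default
    initial <- system_state(s = get0("s0", params$n_total),
                            e = get0("e0", 0),
                            d = get0("d0", 0),
                            i = get0("i0", 0))
  }
  list(params = params, initial = initial,
       t_end = if ("t_end" %in% names(raw)) raw[["t_end"]] else NULL)
}
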