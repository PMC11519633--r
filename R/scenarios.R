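# Registry of the published figure scenarios. Parameter sets are transcribed
# from the figure captions; N = 100 (printed as S0 = 100 only for the first
# time-course figure) and the invasion initial state S0 = N, E0 = 0, D0 = 0,
# I0 = 1 are filled in for every scenario. gamma printed as 1/20 and 1/10 is
# stored as 0.05 and 0.1. The fig10a caption prints only p = sigma/mu = 0.99;
# it is realized here as mu = 0.05, sigma = 0.0495.

scenario_table <- function() {
  tibble::tribble(
    ~scenario_id, ~model, ~eta, ~beta, ~gamma, ~mu,   ~alpha, ~sigma, ~target,   ~expected_regime,
    "fig5",   "sei",  0.05, 0.5, 0.05, 0.05,  0.01,  0,      "free",    "free_stable",
    "fig6a",  "sei",  0.05, 0.5, 0.05, 0.05,  0.01,  0,      "free",    "free_stable",
    "fig6b",  "sei",  4,    0.5, 0.05, 0.05,  0.01,  0,      "free",    "free_saddle",
    "fig7a",  "sei",  4,    0.5, 0.05, 0.05,  0.01,  0,      "endemic", "endemic_node",
    "fig7c",  "sei",  2,    0.5, 0.1,  0.005, 0.001, 0,      "endemic", "endemic_focus",
    "fig8",   "sedi", 4,    0.5, 0.05, 0.05,  0.01,  0.049,  "free",    "free_stable",
    "fig9",   "sedi", 0.05, 0.5, 0.05, 0.05,  0.01,  0.049,  "free",    "free_stable",
    "fig10a", "sedi", 4,    0.5, 0.05, 0.05,  0.01,  0.0495, "free",    "free_stable",
    "fig10b", "sedi", 0.05, 0.5, 0.05, 0.05,  0.01,  0.049,  "free",    "free_stable",
    "fig11a", "sedi", 4,    0.5, 0.05, 0.05,  0.01,  0.04,   "endemic", "endemic_node",
    "fig11c", "sedi", 2,    0.5, 0.1,  0.005, 0.001, 0.001,  "endemic", "endemic_focus"
  )
}

SCENARIO_N <- 100
SCENARIO_I0 <- 1

#' List the registered figure scenarios
#'
#' One row per scenario: model, caption-transcribed rate constants, the
#' equilibrium each figure portrays (`target`), its stated regime, and the
#' derived `r0`, `p` and `p_critical`.
#'
#' @return A tibble with one row per scenario.
#' @examples
#' list_scenarios()
#' @export
list_scenarios <- function() {
  tab <- scenario_table()
  dplyr::mutate(tab,
    n_total = SCENARIO_N,
    r0 = .data$eta * .data$beta / .data$gamma,
    p = .data$sigma / .data$mu,
    p_critical = ifelse(.data$r0 > 0, 1 - 1 / .data$r0, NA_real_)
  )
}

#' Retrieve a figure scenario
#'
#' @param scenario_id One of the ids in [list_scenarios()], e.g. `"fig8"`.
#' @return A `scenario_spec` list: `scenario_id`, `model`, `params`
#'   ([model_params()] with `n_total = 100`), `initial` (the invasion state
#'   `S0 = N, E0 = 0, D0 = 0, I0 = 1`), `target` (which equilibrium the
#'   figure portrays) and `expected_regime`.
#' @examples
#' get_scenario("fig8")$params
#' @export
get_scenario <- function(scenario_id) {
  tab <- scenario_table()
  row <- tab[tab$scenario_id == scenario_id, ]
  if (nrow(row) != 1L) {
    stop("unknown scenario `", scenario_id, "`; available: ",
         paste(tab$scenario_id, collapse = ", "), call. = FALSE)
  }
  params <- model_params(eta = row$eta, beta = row$beta, gamma = row$gamma,
                         mu = row$mu, alpha = row$alpha, sigma = row$sigma,
                         n_total = SCENARIO_N)
  structure(
    list(scenario_id = row$scenario_id,
         model = row$model,
         params = params,
         initial = system_state(s = SCENARIO_N, i = SCENARIO_I0),
         target = row$target,
         expected_regime = row$expected_regime),
    class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario %s> %s model, expected %s (%s equilibrium)\n",
              x$scenario_id, toupper(x$model), x$expected_regime, x$target))
  print(x$params)
  invisible(x)
}

regime_of <- function(target, classification) {
  if (target == "free") {
    switch(classification,
           stable_node = , stable_focus = "free_stable",
           saddle = "free_saddle",
           classification)
  } else {
    switch(classification,
           stable_node = "endemic_node",
           stable_focus = "endemic_focus",
           classification)
  }
}

#' Run a figure scenario end to end
#'
#' Simulates the scenario from its invasion initial state, computes both
#' equilibria and their stability reports, derives the regime verdict from
#' the classification of the equilibrium the figure portrays, and checks
#' it against the caption-stated regime. When the verdict names a stable
#' attractor, the trajectory's limit is additionally audited against that
#' equilibrium's coordinates.
#'
#' @param scenario_id A registered scenario id, or a `scenario_spec`.
#' @param t_end Integration horizon in days.
#' @param ... Further arguments passed to [simulate_model()].
#' @return A `scenario_result` list: `scenario` (the spec), `trajectory`,
#'   `equilibria` (two-row table), `stability` (list of two
#'   [stability_report()]s), `verdict`, `expected_regime`, `match`
#'   (logical), `limit_state` (from [detect_equilibrium()], may be `NULL`).
#' @examples
#' res <- run_scenario("fig8", t_end = 3000)
#' res$verdict
#' @export
run_scenario <- function(scenario_id, t_end = 5000, ...) {
  sc <- if (inherits(scenario_id, "scenario_spec")) scenario_id
        else get_scenario(scenario_id)
  traj <- simulate_model(sc$params, model = sc$model, initial = sc$initial,
                         t_end = t_end, ...)
  eq <- equilibria(sc$params, sc$model)
  reports <- list(
    free = stability_report(sc$params, eq[1, ], model = sc$model),
    endemic = stability_report(sc$params, eq[2, ], model = sc$model)
  )
  verdict <- regime_of(sc$target, reports[[sc$target]]$classification)
  structure(
    list(scenario = sc,
         trajectory = traj,
         equilibria = eq,
         stability = reports,
         verdict = verdict,
         expected_regime = sc$expected_regime,
         match = identical(verdict, sc$expected_regime),
         limit_state = detect_equilibrium(traj, tol = 1e-6)),
    class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result %s> verdict %s (expected %s): %s\n",
              x$scenario$scenario_id, x$verdict, x$expected_regime,
              if (x$match) "match" else "MISMATCH"))
  cat(sprintf("  R0 = %g, p = %g, threshold = %s\n",
              x$equilibria$r0[1], x$equilibria$p[1],
              format(x$equilibria$p_critical[1])))
  if (!is.null(x$limit_state)) {
    s <- x$limit_state
    cat(sprintf("  trajectory limit: (S, E, D, I) = (%.4g, %.4g, %.4g, %.4g)\n",
                s[["s"]], s[["e"]], s[["d"]], s[["i"]]))
  }
  invisible(x)
}
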