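#' Phase diagram of endemic vs insect-free outcomes over (R0, p)
#'
#' Sweeps a grid of reproduction numbers and defended fractions and
#' records, per cell, the analytic outcome (endemic iff `R0 > 1` and
#' `p < 1 - 1/R0`) and optionally the simulated outcome (long-horizon
#' integration from the invasion state; endemic iff the final insect count
#' exceeds `i_cutoff`). The two layers visualize and verify the
#' herd-defense threshold: away from the boundary band they must agree
#' everywhere.
#'
#' The grid is realized by fixing `beta`, `gamma`, `mu`, `alpha` and `N`
#' and solving `eta = r0 * gamma / beta`, `sigma = p * mu` per cell.
#'
#' @param r0_range Length-2 numeric range of reproduction numbers (> 0).
#' @param p_range Length-2 numeric range of defended fractions in `[0, 1]`.
#' @param resolution Cells per axis (>= 2).
#' @param seed Optional integer seed; governs only the jitter of off-grid
#'   test points when `jitter > 0`.
#' @param jitter Half-width of uniform jitter applied to each cell's
#'   `(r0, p)` within its grid spacing (0 = exact lattice).
#' @param simulate Compute the simulated layer (the analytic layer alone is
#'   instantaneous).
#' @param t_end Integration horizon per cell, days.
#' @param i_cutoff Final insect count above which a cell is `"endemic"`.
#' @param beta,gamma,mu,alpha,n_total Fixed background rates realizing the
#'   grid.
#' @param boundary_band Half-width in `p` of the band around
#'   `p = 1 - 1/R0` excluded from the agreement score.
#' @return A `phase_diagram` tibble with columns `r0`, `p`, `eta`, `sigma`,
#'   `p_critical`, `outcome_analytic`, `outcome_simulated` (`NA` when
#'   `simulate = FALSE`), `near_boundary`; attribute `agreement` (fraction
#'   of off-boundary cells where the layers agree, also via
#'   [generics::glance()]).
#' @examples
#' pd <- phase_diagram(c(2, 50), c(0, 1), resolution = 4, t_end = 2000)
#' glance(pd)
#' @export
phase_diagram <- function(r0_range = c(2, 50), p_range = c(0, 1),
                          resolution = 10, seed = NULL, jitter = 0,
                          simulate = TRUE, t_end = 5000, i_cutoff = 1e-3,
                          beta = 0.5, gamma = 0.05, mu = 0.05, alpha = 0.01,
                          n_total = 100, boundary_band = 0.01) {
  stopifnot(length(r0_range) == 2L, length(p_range) == 2L,
            all(r0_range > 0), all(p_range >= 0), all(p_range <= 1),
            resolution >= 2)
  if (!is.null(seed)) set.seed(seed)
  r0_axis <- seq(r0_range[1], r0_range[2], length.out = resolution)
  p_axis <- seq(p_range[1], p_range[2], length.out = resolution)
  grid <- tidyr::expand_grid(r0 = r0_axis, p = p_axis)
  if (jitter > 0) {
    dr <- diff(r0_range) / (resolution - 1) * jitter
    dp <- diff(p_range) / (resolution - 1) * jitter
    grid$r0 <- pmax(grid$r0 + stats::runif(nrow(grid), -dr, dr), 1e-6)
    grid$p <- pmin(pmax(grid$p + stats::runif(nrow(grid), -dp, dp), 0), 1)
  }

  grid <- dplyr::mutate(grid,
    eta = .data$r0 * gamma / beta,
    sigma = .data$p * mu,
    p_critical = 1 - 1 / .data$r0,
    outcome_analytic = ifelse(.data$r0 > 1 & .data$p < .data$p_critical,
                              "endemic", "free"),
    near_boundary = abs(.data$p - .data$p_critical) <= boundary_band
  )

  if (simulate) {
    grid$outcome_simulated <- purrr::pmap_chr(
      grid[, c("eta", "sigma")],
      function(eta, sigma) {
        params <- model_params(eta = eta, beta = beta, gamma = gamma,
                               mu = mu, alpha = alpha, sigma = sigma,
                               n_total = n_total)
        traj <- simulate_model(params, "sedi", t_end = t_end)
        if (traj$I[nrow(traj)] > i_cutoff) "endemic" else "free"
      })
  } else {
    grid$outcome_simulated <- NA_character_
  }

  off <- !grid$near_boundary & !is.na(grid$outcome_simulated)
  agreement <- if (any(off)) {
    mean(grid$outcome_analytic[off] == grid$outcome_simulated[off])
  } else NA_real_
  attr(grid, "agreement") <- agreement
  attr(grid, "boundary_band") <- boundary_band
  class(grid) <- c("phase_diagram", class(grid))
  grid
}
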