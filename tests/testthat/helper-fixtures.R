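# Shared fixtures: the published caption parameter sets and random draws of
# valid parameters/states for property-style tests.

fig5_params <- function() {
  model_params(eta = 0.05, beta = 0.5, gamma = 0.05, mu = 0.05,
               alpha = 0.01, sigma = 0, n_total = 100)
}

fig7a_params <- function() {
  model_params(eta = 4, beta = 0.5, gamma = 0.05, mu = 0.05,
               alpha = 0.01, sigma = 0, n_total = 100)
}

fig7c_params <- function() {
  model_params(eta = 2, beta = 0.5, gamma = 0.1, mu = 0.005,
               alpha = 0.001, sigma = 0, n_total = 100)
}

fig8_params <- function() {
  model_params(eta = 4, beta = 0.5, gamma = 0.05, mu = 0.05,
               alpha = 0.01, sigma = 0.049, n_total = 100)
}

fig11a_params <- function() {
  model_params(eta = 4, beta = 0.5, gamma = 0.05, mu = 0.05,
               alpha = 0.01, sigma = 0.04, n_total = 100)
}

# A random valid parameter set. `defended = NA` draws sigma uniformly in
# [0, mu]; defended = FALSE forces sigma = 0 (SEI-compatible).
draw_params <- function(defended = NA) {
  mu <- runif(1, 0.001, 0.2)
  sigma <- if (isFALSE(defended)) 0 else runif(1, 0, mu)
  model_params(eta = runif(1, 0.01, 5),
               beta = runif(1, 0.01, 1),
               gamma = runif(1, 0.01, 0.5),
               mu = mu,
               alpha = runif(1, 0, 0.1),
               sigma = sigma,
               n_total = runif(1, 10, 1000))
}

# A random state on the conservation manifold s + e + d = n_total.
draw_state <- function(params, defended = NA) {
  w <- runif(3)
  if (isFALSE(defended)) w[3] <- 0
  w <- w / sum(w) * params$n_total
  system_state(s = w[1], e = w[2], d = w[3], i = runif(1, 0, 50))
}

# Independent central finite-difference approximation of the reduced
# (S, E, I) Jacobian, built directly on the public RHS.
fd_jacobian <- function(params, point, h = NULL) {
  if (is.null(h)) h <- 1e-6 * params$n_total
  reduced <- function(v) {
    r <- sedi_rhs(system_state(s = v[1], e = v[2], d = point[["d"]],
                               i = v[3]), params)
    r[c("ds", "de", "di")]
  }
  v0 <- c(point[["s"]], point[["e"]], point[["i"]])
  j <- matrix(0, 3, 3)
  for (k in 1:3) {
    up <- v0; up[k] <- up[k] + h
    dn <- v0; dn[k] <- dn[k] - h
    j[, k] <- (reduced(up) - reduced(dn)) / (2 * h)
  }
  j
}
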