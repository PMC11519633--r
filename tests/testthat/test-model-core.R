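test_that("parameter validation is eager and catches inconsistent rates", {
  expect_error(model_params(eta = 4, beta = 0.5, gamma = 0), "gamma")
  expect_error(model_params(eta = -1, beta = 0.5, gamma = 0.05), "nonnegative")
  expect_error(model_params(eta = 4, beta = 0.5, gamma = 0.05, n_total = 0),
               "n_total")
  expect_error(model_params(eta = 4, beta = 0.5, gamma = 0.05,
                            mu = 0.05, sigma = 0.06), "sigma")
  expect_error(model_params(eta = 4, beta = 0.5, gamma = 0.05,
                            mu = 0, sigma = 0.01), "mu")
  # no vital dynamics (mu = sigma = 0) is a legal configuration
  expect_s3_class(model_params(eta = 4, beta = 0.5, gamma = 0.05),
                  "model_params")
})

test_that("SEI rates match term-by-term hand arithmetic", {
  p <- fig7a_params()
  # free state is a fixed point by construction
  expect_equal(unname(sei_rhs(system_state(s = 100), p)), c(0, 0, 0))
  # eta*I*S/N = 4*10*50/100 = 20; mu*N = 5; mu*S = 2.5; alpha*E = 0.5
  r <- sei_rhs(system_state(s = 50, e = 50, i = 10), p)
  expect_equal(unname(r), c(5 - 20 - 2.5 + 0.5,
                            20 - (0.05 + 0.01) * 50,
                            0.5 * 20 - 0.05 * 10))
  expect_equal(unname(r), c(-17, 17, 9.5))
})

test_that("SEI right-hand side rejects model mismatches", {
  p <- fig7a_params()
  expect_error(sei_rhs(system_state(s = 50, d = 50), p), "d = 0")
  expect_error(sei_rhs(system_state(s = 100), fig8_params()), "sigma")
})

test_that("SEDI rates match hand arithmetic and zero out at Q*_Free", {
  p <- fig8_params()
  # Q*_Free = ((1-p)N, 0, 0) with D* = pN; p = 0.98
  expect_equal(unname(sedi_rhs(system_state(s = 2, d = 98), p)),
               c(0, 0, 0, 0), tolerance = 1e-12)
  # independent term-by-term oracle at an interior state
  s <- 50; e <- 25; d <- 25; i <- 10
  force <- 4 * i * s / 100
  expect_equal(unname(sedi_rhs(system_state(s, e, d, i), p)),
               c((0.05 - 0.049) * 100 - force - 0.05 * s + 0.01 * e,
                 force - (0.05 + 0.01) * e,
                 0.049 * 100 - 0.05 * d,
                 0.5 * force - 0.05 * i))
})

test_that("SEDI reduces to SEI at sigma = 0, componentwise", {
  set.seed(42)
  for (rep in 1:25) {
    p <- draw_params(defended = FALSE)
    st <- draw_state(p, defended = FALSE)
    sei <- sei_rhs(st, p)
    sedi <- sedi_rhs(st, p)
    expect_identical(unname(sedi[c("ds", "de", "di")]), unname(sei))
    expect_identical(unname(sedi[["dd"]]), 0)
  }
})

test_that("plant-compartment rates sum to zero on the manifold", {
  set.seed(7)
  for (rep in 1:50) {
    p <- draw_params()
    st <- draw_state(p)
    r <- sedi_rhs(st, p)
    scale <- p$mu * p$n_total + abs(r[["ds"]])
    expect_lt(abs(r[["ds"]] + r[["de"]] + r[["dd"]]), 1e-12 * max(scale, 1))
    p0 <- draw_params(defended = FALSE)
    st0 <- draw_state(p0, defended = FALSE)
    r0 <- sei_rhs(st0, p0)
    expect_lt(abs(r0[["ds"]] + r0[["de"]]),
              1e-12 * max(p0$mu * p0$n_total + abs(r0[["ds"]]), 1))
  }
})

test_that("reproduction number is eta*beta/gamma", {
  expect_equal(reproduction_number(fig5_params()), 0.5)
  expect_equal(reproduction_number(fig7a_params()), 40)
  expect_equal(reproduction_number(
    model_params(eta = 4, beta = 0, gamma = 0.05)), 0)
})

test_that("defended fraction is sigma/mu with the no-germination convention", {
  expect_equal(defended_fraction(fig8_params()), 0.98)
  expect_equal(defended_fraction(fig7a_params()), 0)
  expect_equal(defended_fraction(
    model_params(eta = 1, beta = 1, gamma = 1, mu = 0.03, sigma = 0.03)), 1)
  expect_equal(defended_fraction(model_params(eta = 1, beta = 1, gamma = 1)), 0)
})

test_that("critical defense threshold is 1 - 1/R0", {
  expect_equal(critical_threshold(500), 0.998)
  expect_equal(critical_threshold(1), 0)
  expect_equal(critical_threshold(40), 0.975)
  expect_error(critical_threshold(0), "positive")
  expect_error(critical_threshold(-2), "positive")
  # strictly increasing in r0 and bounded above by 1
  r0 <- sort(exp(runif(50, log(0.01), log(1e6))))
  th <- critical_threshold(r0)
  expect_true(all(diff(th) > 0))
  expect_true(all(th < 1))
  expect_true(all(th[r0 <= 1] <= 0))
})

test_that("insect growth at onset matches S > N*gamma/(eta*beta)", {
  p_hi <- fig7a_params()  # R0 = 40, cutoff N*gamma/(eta*beta) = 2.5
  expect_true(insect_growth_at_onset(system_state(s = 100, i = 1), p_hi))
  expect_true(insect_growth_at_onset(system_state(s = 3, i = 1), p_hi))
  expect_false(insect_growth_at_onset(system_state(s = 2, i = 1), p_hi))
  p_lo <- fig5_params()   # R0 = 0.5 < 1: no growth even at S = N
  expect_false(insect_growth_at_onset(system_state(s = 100, i = 1), p_lo))
  expect_error(insect_growth_at_onset(system_state(s = 100, i = 0), p_hi),
               "vacuous")
})

test_that("onset condition agrees with the sign of the insect rate", {
  set.seed(11)
  for (rep in 1:50) {
    p <- draw_params()
    st <- draw_state(p)
    if (st[["i"]] <= 0) next
    di <- sedi_rhs(st, p)[["di"]]
    if (abs(di) < 1e-12) next  # boundary: sign undefined numerically
    expect_identical(insect_growth_at_onset(st, p), di > 0)
  }
})

test_that("configuration files round-trip parameters and initial state", {
  path <- system.file("extdata", "example-config.yaml",
                      package = "plantdefense")
  cfg <- read_params_config(path)
  expect_equal(cfg$params$eta, 4)
  expect_equal(cfg$params$sigma, 0.049)
  expect_equal(cfg$t_end, 5000)
  expect_equal(unname(cfg$initial[c("s", "e", "d", "i")]), c(100, 0, 0, 1))
})
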