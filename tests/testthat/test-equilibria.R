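test_that("SEI free equilibrium is (N, 0, 0) and a fixed point", {
  eq <- sei_free_equilibrium(fig7a_params())
  expect_equal(c(eq$s_star, eq$e_star, eq$d_star, eq$i_star), c(100, 0, 0, 0))
  expect_true(eq$exists)
  eq1 <- sei_free_equilibrium(model_params(eta = 1, beta = 1, gamma = 1,
                                           n_total = 1))
  expect_equal(eq1$s_star, 1)
})

test_that("SEI endemic equilibrium matches the closed form", {
  # R0 = 40: (N/R0, N(R0-1)/R0, N(mu+alpha)(R0-1)/eta)
  eq <- sei_endemic_equilibrium(fig7a_params())
  expect_equal(c(eq$s_star, eq$e_star, eq$i_star), c(2.5, 97.5, 58.5))
  expect_true(eq$exists)
  # R0 = 10 variant
  eq2 <- sei_endemic_equilibrium(fig7c_params())
  expect_equal(c(eq2$s_star, eq2$e_star, eq2$i_star), c(10, 90, 2.7))
  expect_true(eq2$exists)
  # R0 = 1: degenerates onto the free equilibrium, flagged non-existing
  pb <- model_params(eta = 0.1, beta = 0.5, gamma = 0.05, mu = 0.05,
                     alpha = 0.01, n_total = 100)
  expect_equal(reproduction_number(pb), 1)
  eqb <- sei_endemic_equilibrium(pb)
  expect_equal(c(eqb$s_star, eqb$e_star, eqb$i_star), c(100, 0, 0))
  expect_false(eqb$exists)
})

test_that("SEDI free equilibrium splits plants by the defended fraction", {
  eq <- sedi_free_equilibrium(fig8_params())
  expect_equal(c(eq$s_star, eq$e_star, eq$d_star, eq$i_star), c(2, 0, 98, 0))
  expect_true(eq$exists)
  # sigma = 0 reduces to the SEI free equilibrium
  eq0 <- sedi_free_equilibrium(fig7a_params())
  expect_equal(eq0$s_star, 100)
  expect_equal(eq0$d_star, 0)
  # full defense: every plant defended
  pf <- model_params(eta = 4, beta = 0.5, gamma = 0.05, mu = 0.05,
                     sigma = 0.05, n_total = 100)
  eqf <- sedi_free_equilibrium(pf)
  expect_equal(c(eqf$s_star, eqf$d_star), c(0, 100))
})

test_that("SEDI endemic equilibrium matches the closed form and flags", {
  # R0 = 40, p = 0.8, margin 1 - p - 1/R0 = 0.175
  eq <- sedi_endemic_equilibrium(fig11a_params())
  expect_equal(c(eq$s_star, eq$e_star, eq$i_star), c(2.5, 17.5, 10.5))
  expect_equal(eq$d_star, 80)
  expect_true(eq$exists)
  # exactly at the threshold: coincides with Q*_Free, flagged non-existing
  pt <- model_params(eta = 4, beta = 0.5, gamma = 0.05, mu = 0.05,
                     sigma = 0.05 * 0.975, alpha = 0.01, n_total = 100)
  eqt <- sedi_endemic_equilibrium(pt)
  expect_equal(eqt$e_star, 0, tolerance = 1e-10)
  expect_equal(eqt$i_star, 0, tolerance = 1e-10)
  expect_false(eqt$exists)
  # above the threshold: negative components, flagged non-existing
  eq8 <- sedi_endemic_equilibrium(fig8_params())
  expect_lt(eq8$e_star, 0)
  expect_lt(eq8$i_star, 0)
  expect_false(eq8$exists)
})

test_that("endemic existence follows R0 > 1 and p < 1 - 1/R0", {
  expect_false(endemic_exists(fig8_params(), "sedi"))    # p = 0.98 > 0.975
  expect_true(endemic_exists(fig11a_params(), "sedi"))   # p = 0.80 < 0.975
  expect_false(endemic_exists(fig5_params(), "sei"))     # R0 = 0.5
  expect_true(endemic_exists(fig7a_params(), "sei"))
  # contract with the equilibrium exists flag, over random draws
  set.seed(13)
  for (rep in 1:50) {
    p <- draw_params()
    expect_identical(endemic_exists(p, "sedi"),
                     sedi_endemic_equilibrium(p)$exists)
    p0 <- draw_params(defended = FALSE)
    expect_identical(endemic_exists(p0, "sei"),
                     sei_endemic_equilibrium(p0)$exists)
  }
})

test_that("every existing equilibrium zeroes the model right-hand side", {
  set.seed(101)
  checked <- 0
  for (rep in 1:120) {
    p <- draw_params()
    n <- p$n_total
    for (eq in list(sedi_free_equilibrium(p), sedi_endemic_equilibrium(p))) {
      if (!eq$exists) next
      r <- sedi_rhs(system_state(s = eq$s_star, e = eq$e_star,
                                 d = eq$d_star, i = eq$i_star), p)
      expect_lt(max(abs(r)), 1e-10 * n)
      expect_equal(eq$s_star + eq$e_star + eq$d_star, n, tolerance = 1e-12)
      checked <- checked + 1
    }
    p0 <- draw_params(defended = FALSE)
    for (eq in list(sei_free_equilibrium(p0), sei_endemic_equilibrium(p0))) {
      if (!eq$exists) next
      r <- sei_rhs(system_state(s = eq$s_star, e = eq$e_star, i = eq$i_star),
                   p0)
      expect_lt(max(abs(r)), 1e-10 * p0$n_total)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 100)
})

test_that("endemic components share the sign of 1 - p - 1/R0", {
  set.seed(29)
  for (rep in 1:50) {
    p <- draw_params()
    r0 <- reproduction_number(p)
    if (r0 <= 0) next
    margin <- 1 - defended_fraction(p) - 1 / r0
    eq <- sedi_endemic_equilibrium(p)
    expect_identical(sign(eq$e_star), sign(margin))
    expect_identical(sign(eq$i_star), sign(margin))
  }
})

test_that("SEDI equilibria at sigma = 0 coincide with SEI equilibria", {
  set.seed(31)
  for (rep in 1:20) {
    p <- draw_params(defended = FALSE)
    if (reproduction_number(p) <= 0) next
    a <- sedi_endemic_equilibrium(p)
    b <- sei_endemic_equilibrium(p)
    expect_equal(c(a$s_star, a$e_star, a$d_star, a$i_star),
                 c(b$s_star, b$e_star, b$d_star, b$i_star))
    expect_identical(a$exists, b$exists)
  }
})

test_that("equilibria() assembles the CSV-ready two-row table", {
  tab <- equilibria(fig7a_params(), "sei")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$label, c("sei_free", "sei_endemic"))
  expect_true(all(c("s_star", "e_star", "d_star", "i_star", "exists",
                    "r0", "p", "p_critical") %in% names(tab)))
  expect_equal(tab$r0, c(40, 40))
  tab2 <- equilibria(fig8_params(), "sedi")
  expect_equal(tab2$label, c("sedi_free", "sedi_endemic"))
  expect_equal(tab2$p, c(0.98, 0.98))
})
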