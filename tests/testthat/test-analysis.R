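test_that("Hill-curve fitting recovers noiseless generating parameters", {
  d <- default_aba_levels(12, 0.1, 100)
  y <- 48 * d^2 / (25 + d^2)
  f <- fit_hill(d, y)
  expect_equal(unname(coef(f)), c(48, 5, 2), tolerance = 1e-4)
  expect_lt(f$rss, 1e-8)
  expect_equal(f$r2, 1, tolerance = 1e-10)
  expect_equal(predict(f, 5), 24, tolerance = 1e-3)
})

test_that("Hill fitting rejects degenerate or insufficient data", {
  expect_error(fit_hill(c(1, 2, 4, 8), rep(3.3, 4)), "degenerate")
  expect_error(fit_hill(c(5, 5, 5, 5), c(1, 2, 3, 4)), "4 distinct")
  expect_error(fit_hill(c(1, 2, 4), c(1, 2, 3)), "4 distinct")
  expect_error(fit_hill(c(1, 2, 4, 8), c(1, 2, NA, 4)), "finite")
})

test_that("Hill fitting is scale-equivariant in the response", {
  set.seed(31)
  d <- default_aba_levels(10, 0.2, 80)
  y <- 10 * d^1.5 / (3^1.5 + d^1.5) + rnorm(10, 0, 0.05)
  f1 <- coef(fit_hill(d, y))
  f2 <- coef(fit_hill(d, 100 * y))
  expect_equal(f2[["top"]], 100 * f1[["top"]], tolerance = 1e-4)
  expect_equal(f2[["K_half"]], f1[["K_half"]], tolerance = 1e-4)
  expect_equal(f2[["n"]], f1[["n"]], tolerance = 1e-4)
})

test_that("linearity check reproduces an exact line and handles flat data", {
  tab <- data.frame(aba_initial = 1:4, I_final = 0.5 * (1:4) + 2)
  lf <- linearity_check(tab)
  expect_equal(lf$slope, 0.5)
  expect_equal(lf$intercept, 2)
  expect_equal(lf$r2, 1)

  flat <- data.frame(aba_initial = 1:4, I_final = rep(7, 4))
  expect_warning(lf0 <- linearity_check(flat), "zero variance")
  expect_identical(lf0$slope, 0)
  expect_identical(lf0$r2, 0)

  expect_error(linearity_check(tab[1:2, ]), "at least 3")
})

test_that("homogeneous steady states have unit elasticities and absent parameters none", {
  p <- prod_deg_only(0.05, 0.025)
  s <- local_sensitivity("biosensor", p,
                         output_spec = list(quantity = "steady",
                                            variable = "C_ABA"),
                         settings = solver_settings(t_end = 2000),
                         param_names = c("k_prod", "k_deg",
                                         "k_interact_SNRK2"))
  expect_equal(s["k_prod", 1L], 1, tolerance = 1e-3)
  expect_equal(s["k_deg", 1L], -1, tolerance = 1e-3)
  expect_identical(s["k_interact_SNRK2", 1L], 0)
})

test_that("sensitivity coefficients converge at second order in the perturbation", {
  p <- biosensor_params()
  get_S <- function(h) {
    local_sensitivity("biosensor", p,
                      output_spec = list(quantity = "final",
                                         variable = "I_biolum"),
                      perturbation = h,
                      settings = solver_settings(rel_tol = 1e-10,
                                                 abs_tol = 1e-12,
                                                 t_end = 300),
                      param_names = "K_half")[1L, 1L]
  }
  d1 <- abs(get_S(0.2) - get_S(0.1))
  d2 <- abs(get_S(0.1) - get_S(0.05))
  expect_gt(d1 / d2, 2.5)
  expect_lt(d1 / d2, 6)
})

test_that("normalized sensitivities do not depend on the kon unit convention", {
  a <- local_sensitivity("biosensor", biosensor_params(kon = 0.1),
                         settings = solver_settings(t_end = 300),
                         param_names = "kon")
  b <- local_sensitivity("biosensor", biosensor_params(kon_M = 1e5),
                         settings = solver_settings(t_end = 300),
                         param_names = "kon")
  expect_equal(a[1L, 1L], b[1L, 1L], tolerance = 1e-12)
})

test_that("sensitivity analysis rejects undefined normalizations and bad perturbations", {
  expect_error(
    local_sensitivity("biosensor", biosensor_params(k_response = 0),
                      settings = solver_settings(t_end = 100)),
    "base output is 0")
  expect_error(local_sensitivity("biosensor", perturbation = 0.7),
               "perturbation")
  expect_error(local_sensitivity("biosensor",
                                 output_spec = list(quantity = "final",
                                                    variable = "SNRK2")),
               "not a state")
})
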