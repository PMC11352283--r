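test_that("adaptive integration reproduces first-order decay to 1e-6 relative", {
  tr <- integrate_model("biosensor", decay_only(0.1), zero_bio_init(1),
                        solver_settings(t_end = 10))
  C_final <- unname(tr$states[nrow(tr$states), 1L])
  expect_equal(C_final, exp(-1), tolerance = 1e-6)
  expect_identical(unname(tr$states[1L, ]), unname(zero_bio_init(1)))
  expect_true(all(diff(tr$times) > 0))
  expect_equal(nrow(tr$states), 200L)
})

test_that("the ABA balance stays at its production/loss equilibrium", {
  p <- signaling_params()
  init <- c(C_ABA = p$k_synthesis / p$K1, SNRK2 = 0, PP2C = 0, MAPK = 0)
  tr <- integrate_model("signaling_aba", p, init,
                        solver_settings(t_end = 50))
  expect_true(all(abs(tr$states[, 1L] - init[["C_ABA"]]) < 1e-8))
})

test_that("adaptive and RK4-oracle trajectories agree for the ABA-free protein network", {
  set.seed(21)
  init <- c(C_ABA = 0, SNRK2 = runif(1, 0, 2), PP2C = runif(1, 0, 2),
            MAPK = runif(1, 0, 2))
  a <- integrate_model("signaling_noaba", NULL, init,
                       solver_settings(t_end = 20))
  b <- rk4_reference("signaling_noaba", NULL, init, dt = 1e-3, t_end = 20)
  expect_lt(rel_sup_err(a, b), 1e-6)
})

test_that("the RK4 oracle has its textbook properties", {
  # closed-form accuracy at dt = 0.01
  tr <- rk4_reference("biosensor", decay_only(0.1), zero_bio_init(1),
                      dt = 0.01, t_end = 10, n_report = 2)
  expect_equal(unname(tr$states[2L, 1L]), exp(-1), tolerance = 1e-8)

  # 4th-order convergence: halving dt shrinks the error ~16x
  errs <- vapply(c(0.5, 0.25), function(dt) {
    t2 <- rk4_reference("biosensor", decay_only(0.1), zero_bio_init(1),
                        dt = dt, t_end = 10, n_report = 2)
    abs(t2$states[2L, 1L] - exp(-1))
  }, numeric(1))
  expect_gt(errs[1L] / errs[2L], 12)
  expect_lt(errs[1L] / errs[2L], 20)

  # exact in one step when the RHS is constant in time
  t3 <- rk4_reference("biosensor", prod_deg_only(0.3, 0), zero_bio_init(0),
                      dt = 7, t_end = 7, n_report = 2)
  expect_equal(unname(t3$states[2L, 1L]), 0.3 * 7, tolerance = 1e-14)

  expect_error(rk4_reference("biosensor", dt = 1e-9, t_end = 100),
               "1e7")
})

test_that("steady-state detection finds the production/degradation balance and flags non-equilibria", {
  st <- run_to_steady("biosensor", prod_deg_only(0.05, 0.025),
                      zero_bio_init(0),
                      solver_settings(t_end = 2000))
  expect_true(st$converged)
  expect_equal(st$state[["C_ABA"]], 2, tolerance = 1e-6)
  expect_lt(st$t_reached, 2000)

  # persistent SnRK2 activation never equilibrates
  ns <- run_to_steady("signaling_aba", signaling_params(),
                      settings = solver_settings(t_end = 100))
  expect_false(ns$converged)
  expect_identical(ns$t_reached, 100)

  # a dead system is steady from the start
  z <- run_to_steady("biosensor", prod_deg_only(0, 0), zero_bio_init(0))
  expect_true(z$converged)
  expect_identical(z$t_reached, 0)
})

test_that("binding conservation laws hold along integrated mass-action trajectories", {
  init <- c(C_ABA = 5, mRNA = 1, Protein = 2, Complex = 0, I_biolum = 0)
  tr1 <- integrate_model("biosensor", biosensor_params(k_prod = 0,
                                                       k_deg = 0),
                         init, solver_settings(t_end = 500))
  tot1 <- tr1$states[, 1L] + tr1$states[, 4L]
  expect_lt(max(abs(tot1 - tot1[1L])), 1e-8)

  tr2 <- integrate_model("biosensor", biosensor_params(k_tran_syn = 0,
                                                       k_deg_prot = 0),
                         init, solver_settings(t_end = 500))
  tot2 <- tr2$states[, 3L] + tr2$states[, 4L]
  expect_lt(max(abs(tot2 - tot2[1L])), 1e-8)
})

test_that("solutions are self-consistent under tolerance tightening", {
  loose <- integrate_model("biosensor", settings = solver_settings(
    rel_tol = 1e-6, abs_tol = 1e-8, t_end = 600))
  tight <- integrate_model("biosensor", settings = solver_settings(
    rel_tol = 1e-8, abs_tol = 1e-10, t_end = 600))
  final_l <- loose$states[nrow(loose$states), ]
  final_t <- tight$states[nrow(tight$states), ]
  expect_lt(max(abs(final_l - final_t) / (1 + abs(final_t))), 1e-6)
})

test_that("trajectories carry their provenance", {
  tr <- integrate_model("biosensor", settings = solver_settings(t_end = 1))
  expect_identical(tr$model_id, "biosensor")
  expect_identical(tr$mode, "mass_action")
  expect_match(tr$params_digest, "kon=0.1")
  sig <- integrate_model("signaling_aba",
                         settings = solver_settings(t_end = 1))
  expect_true(is.na(sig$mode))
  expect_identical(colnames(sig$states),
                   c("C_ABA", "SNRK2", "PP2C", "MAPK"))
})
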