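sig_example <- signaling_params(k_synthesis = 1.0, K1 = 0.5, K2 = 2.0,
                                K3 = 0.1, k_interact_SNRK2 = 0.3,
                                k_interact_PP2C = 0.2,
                                k_interact_MAPK = 0.4, K_half = 1, n = 2)

test_that("ABA-present signaling derivatives match direct substitution", {
  d <- signaling_rhs_with_aba(c(C_ABA = 1, SNRK2 = 2, PP2C = 1,
                                MAPK = 0.5), sig_example)
  expect_equal(unname(d), c(0.5, 1.0, 0.4, -0.1))

  # ABA production/loss balance: C* = k_synthesis / K1
  d2 <- signaling_rhs_with_aba(c(C_ABA = 2, SNRK2 = 5, PP2C = 3,
                                 MAPK = 1), sig_example)
  expect_equal(d2[["C_ABA"]], 0)

  # from rest, only ABA synthesis moves
  d3 <- signaling_rhs_with_aba(c(C_ABA = 0, SNRK2 = 0, PP2C = 0,
                                 MAPK = 0), sig_example)
  expect_equal(unname(d3), c(1, 0, 0, 0))
})

test_that("SnRK2 cannot decrease while ABA is being perceived", {
  set.seed(11)
  for (i in 1:25) {
    st <- c(C_ABA = runif(1, 0, 10), SNRK2 = runif(1, -2, 10),
            PP2C = runif(1, -2, 10), MAPK = runif(1, -2, 10))
    expect_gte(signaling_rhs_with_aba(st, sig_example)[["SNRK2"]], 0)
  }
})

test_that("ABA-free signaling derivatives match direct substitution and conserve mass when PP2C turnover is off", {
  p <- signaling_params(k_interact_SNRK2 = 0.3, k_interact_PP2C = 0,
                        k_interact_MAPK = 0.4)
  d <- signaling_rhs_without_aba(c(C_ABA = 0, SNRK2 = 2, PP2C = 1,
                                   MAPK = 0.5), p)
  expect_equal(d[["PP2C"]], 0.6)
  expect_equal(d[["MAPK"]], -0.2)
  expect_equal(d[["SNRK2"]], -0.4)
  expect_equal(sum(d[c("SNRK2", "PP2C", "MAPK")]), 0)

  # linear homogeneous: the origin is an equilibrium
  z <- signaling_rhs_without_aba(c(C_ABA = 0, SNRK2 = 0, PP2C = 0,
                                   MAPK = 0), sig_example)
  expect_equal(unname(z), c(0, 0, 0, 0))
})

test_that("without ABA the phosphatase can only deactivate SnRK2", {
  set.seed(12)
  for (i in 1:25) {
    st <- c(C_ABA = 0, SNRK2 = runif(1, -5, 10), PP2C = runif(1, 0, 10),
            MAPK = runif(1, -5, 10))
    expect_lte(signaling_rhs_without_aba(st, sig_example)[["SNRK2"]], 0)
  }
})

test_that("biosensor derivatives match direct substitution in both kinetics modes", {
  p <- worked_biosensor_params()
  s <- worked_biosensor_state()
  ma <- biosensor_rhs(s, p, "mass_action")
  expect_equal(unname(ma), c(-0.1495, 0.1, -0.2395, 0.1995, 10 / 3),
               tolerance = 1e-12)
  lit <- biosensor_rhs(s, p, "literal")
  expect_equal(unname(lit), c(0.0005, 0.1, -0.04, 0.0495, 10 / 3),
               tolerance = 1e-12)
  expect_error(biosensor_rhs(s, p, "gillespie"), "mode")
})

test_that("without ligand or complex, only mRNA decay remains active", {
  p <- worked_biosensor_params()
  for (m in c("mass_action", "literal")) {
    d <- biosensor_rhs(c(C_ABA = 0, mRNA = 0.7, Protein = 1, Complex = 0,
                         I_biolum = 3), p, m)
    expect_equal(d[["mRNA"]], -p$k_tran_deg * 0.7)
    expect_equal(d[["I_biolum"]], 0)
    expect_equal(d[["Complex"]], 0)
  }
})

test_that("mass-action binding fluxes conserve ABA and protein totals at the derivative level", {
  set.seed(13)
  p_aba <- biosensor_params(k_prod = 0, k_deg = 0)
  p_prot <- biosensor_params(k_tran_syn = 0, k_deg_prot = 0)
  for (i in 1:20) {
    s <- c(C_ABA = runif(1, 0, 20), mRNA = runif(1, 0, 3),
           Protein = runif(1, 0, 5), Complex = runif(1, 0, 10),
           I_biolum = runif(1, 0, 100))
    d1 <- biosensor_rhs(s, p_aba, "mass_action")
    expect_equal(d1[["C_ABA"]] + d1[["Complex"]], 0, tolerance = 1e-14)
    d2 <- biosensor_rhs(s, p_prot, "mass_action")
    expect_equal(d2[["Protein"]] + d2[["Complex"]], 0, tolerance = 1e-14)
    # cumulative light can never dim
    expect_gte(d1[["I_biolum"]], 0)
    expect_gte(d2[["I_biolum"]], 0)
  }
})

test_that("compiled and R-level right-hand sides integrate to the same place in both kinetics modes", {
  set.seed(14)
  for (i in 1:3) {
    s <- c(C_ABA = runif(1, 0, 20), mRNA = runif(1, 0, 3),
           Protein = runif(1, 0, 5), Complex = runif(1, 0, 10),
           I_biolum = 0)
    for (m in c("mass_action", "literal")) {
      a <- integrate_model("biosensor", NULL, s,
                           solver_settings(t_end = 30, n_report = 10),
                           mode = m)
      b <- rk4_reference("biosensor", NULL, s, dt = 5e-3, t_end = 30,
                         mode = m, n_report = 10)
      expect_lt(rel_sup_err(a, b), 1e-6)
    }
  }
})
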