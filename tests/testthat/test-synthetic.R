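short <- solver_settings(t_end = 600)

test_that("a noiseless plate equals the forward dose-response exactly", {
  dr <- dose_response(default_aba_levels(5), settings = short)
  plate <- generate_dose_response_data(aba_levels = default_aba_levels(5),
                                       noise_sd = 0, seed = 3,
                                       settings = short)
  expect_identical(plate$reading, dr$I_final)
  expect_identical(plate$time, rep(600, 5))
  expect_false(any(plate$flagged_negative))
})

test_that("plates are seed-deterministic and seeds matter", {
  a <- generate_dose_response_data(aba_levels = c(1.5, 10, 50),
                                   replicates = 2, noise_sd = 1, seed = 7,
                                   settings = short)
  b <- generate_dose_response_data(aba_levels = c(1.5, 10, 50),
                                   replicates = 2, noise_sd = 1, seed = 7,
                                   settings = short)
  c <- generate_dose_response_data(aba_levels = c(1.5, 10, 50),
                                   replicates = 2, noise_sd = 1, seed = 8,
                                   settings = short)
  expect_identical(a$reading, b$reading)
  expect_false(identical(a$reading, c$reading))
})

test_that("generation does not disturb the session RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_dose_response_data(aba_levels = c(1.5, 10),
                                        noise_sd = 1, seed = 7,
                                        settings = short))
  expect_identical(runif(1), before)
})

test_that("replicate means obey the law of large numbers at the stated noise", {
  plate <- generate_dose_response_data(aba_levels = 10,
                                       replicates = 1000, noise_sd = 0.5,
                                       seed = 17, settings = short)
  truth <- dose_response(10, settings = short)$I_final
  expect_lt(abs(mean(plate$reading) - truth), 3 * 0.5 / sqrt(1000))
})

test_that("noise is independent across rows", {
  plate <- generate_dose_response_data(aba_levels = 10,
                                       replicates = 10000, noise_sd = 1,
                                       seed = 23, settings = short)
  eps <- plate$reading - mean(plate$reading)
  lag1 <- cor(eps[-1L], eps[-length(eps)])
  expect_lt(abs(lag1), 0.05)
})

test_that("negative readings are kept and flagged, preserving unbiasedness", {
  plate <- generate_dose_response_data(aba_levels = 1.5, replicates = 200,
                                       noise_sd = 1e4, seed = 5,
                                       settings = short)
  expect_true(any(plate$reading < 0))
  expect_identical(plate$flagged_negative, plate$reading < 0)
})

test_that("time-course plates are noiselessly nondecreasing and anchored at zero", {
  tc <- generate_trajectory_data(aba_initial = 5,
                                 sample_times = seq(0, 600, by = 120),
                                 noise_sd = 0, seed = 1)
  expect_true(all(diff(tc$reading) >= 0))
  expect_equal(tc$reading[1L], 0, tolerance = 1e-12)

  single <- generate_trajectory_data(init_state = zero_bio_init(0),
                                     sample_times = 0, noise_sd = 0.1,
                                     seed = 2)
  expect_equal(single$reading, 0, tolerance = 0.5)
  expect_error(generate_trajectory_data(sample_times = c(10, 10)),
               "strictly increasing")
})

test_that("ground truth travels with the plate", {
  p <- biosensor_params(K_half = 2)
  plate <- generate_dose_response_data(p, aba_levels = c(1.5, 10),
                                       noise_sd = 0.5, seed = 9,
                                       settings = short)
  expect_identical(attr(plate, "true_params")$K_half, 2)
  expect_identical(attr(plate, "seed"), 9)
  expect_identical(attr(plate, "noise_sd"), 0.5)
})
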