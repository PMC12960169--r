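test_that("donor panel draws match the requested mean and CV", {
  # degenerate: CV 0 collapses to the mean exactly
  spec0 <- data.frame(factor_name = "F", mean = 42, cv = 0)
  p0 <- simulate_donor_panel(8, spec0, seed = 1)
  expect_identical(p0$F, rep(42, 8))

  # lognormal moment-matching: empirical CV within 1% of target at n = 1e5
  spec <- data.frame(factor_name = "F", mean = 100, cv = 0.473)
  p <- simulate_donor_panel(1e5, spec, seed = 2)
  expect_lt(abs(oracle_cv(p$F) / 0.473 - 1), 0.01)
  expect_lt(abs(mean(p$F) / 100 - 1), 0.01)
  expect_true(all(p$F > 0))
})

test_that("donor panel is reproducible under a fixed seed and validates input", {
  a <- simulate_donor_panel(8, seed = 7)
  b <- simulate_donor_panel(8, seed = 7)
  expect_identical(a, b)
  expect_error(simulate_donor_panel(8, data.frame(factor_name = "F",
                                                  mean = -1, cv = 0.2)),
               "mean")
  expect_error(simulate_donor_panel(8, data.frame(factor_name = "F",
                                                  mean = 1, cv = -0.1)),
               "CV")
})

test_that("CFSE peaks halve per generation and follow the stated mixture", {
  # single-peak case: all events in generation 0, around the centre
  ev0 <- simulate_cfse_events(2000, gen0_center = 1e4,
                              generation_probs = 1, seed = 1)
  expect_true(all(ev0$true_generation == 0))
  expect_lt(abs(median(log10(ev0$fluorescence)) - 4), 0.01)

  # halving arithmetic: generation-3 peak centres at gen0 / 2^3
  ev3 <- simulate_cfse_events(5000, gen0_center = 1e4, peak_spread = 0.01,
                              generation_probs = c(0, 0, 0, 1), seed = 2)
  expect_lt(abs(median(ev3$fluorescence) / 1250 - 1), 0.01)

  # exact geometric halving of expected centres across generations
  centers <- 1e4 / 2^(0:6)
  expect_equal(centers[-1] / centers[-7], rep(0.5, 6))

  # binomial mixture: 50/50 split over generations 0 and 1
  ev <- simulate_cfse_events(1e4, generation_probs = c(0.5, 0.5), seed = 3)
  frac0 <- mean(ev$true_generation == 0)
  expect_lt(abs(frac0 - 0.5), 3 * sqrt(0.25 / 1e4))

  expect_error(simulate_cfse_events(100, generation_probs = c(0.5, 0.4)),
               "sum to 1")
})

test_that("suppression series follows the 4PL exactly when noiseless", {
  doses <- 10^seq(2, 6, length.out = 12)
  dr <- simulate_suppression_series(doses, top = 1, bottom = 0, ic50 = 1e4,
                                    hill = 1.3, noise_sd = 0, n_replicates = 1)
  expect_equal(dr$response,
               four_param_logistic(doses, 1, 0, 1e4, 1.3), tolerance = 1e-12)
  # midpoint by construction and monotone nonincreasing for hill > 0
  expect_equal(four_param_logistic(1e4, 1, 0, 1e4, 2), 0.5)
  expect_true(all(diff(dr$response) <= 0))
  # low-dose limit approaches top
  expect_equal(four_param_logistic(1e-8, 1, 0, 1e4, 1), 1, tolerance = 1e-6)
  expect_error(simulate_suppression_series(c(-1, 10)), "doses")
  expect_error(simulate_suppression_series(top = 0, bottom = 1), "top")
})

test_that("correlated pairs hit the target Pearson rho", {
  # perfect linearity
  p1 <- simulate_correlated_pairs(50, rho = 1, seed = 1)
  expect_equal(cor(p1$surrogate, p1$functional), 1, tolerance = 1e-12)
  # large-sample consistency at the study's rho = -0.9
  p <- simulate_correlated_pairs(1e5, rho = -0.9, seed = 2)
  expect_lt(abs(cor(p$surrogate, p$functional) - (-0.9)), 0.01)
  # means and SDs land on the analysis scale
  expect_lt(abs(mean(p$surrogate) - 50), 0.5)
  expect_lt(abs(sd(p$functional) - 0.4), 0.01)
  expect_error(simulate_correlated_pairs(10, rho = -1.2), "rho")
})

test_that("sim_config validates its components", {
  expect_s3_class(sim_config(seed = 1), "sim_config")
  expect_error(sim_config(n_donors = 0), "n_donors")
  expect_error(sim_config(cfse_spec = list(n_events = 10, gen0_center = 1e4,
                                           peak_spread = 0.05,
                                           generation_probs = c(0.7, 0.2))),
               "sum to 1")
  expect_error(sim_config(pair_spec = list(n_pairs = 5, rho = 2,
                                           means = c(0, 0), sds = c(1, 1))),
               "rho")
})
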