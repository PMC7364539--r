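test_that("OD converts linearly to dry weight at 0.25 mg per OD ml", {
  expect_equal(od_to_dry_weight(1, 1), 0.25)
  expect_equal(od_to_dry_weight(0, 50), 0)
  expect_equal(od_to_dry_weight(0.5, 100), 12.5)
  expect_error(od_to_dry_weight(-0.1, 1), "non-negative")
  expect_error(od_to_dry_weight(1, 0), "positive")
})

test_that("flux and specific activity interconvert at protein fraction 0.5", {
  expect_equal(round(flux_to_specific_activity(0.78)), 26)
  expect_equal(flux_to_specific_activity(0), 0)
  expect_equal(flux_to_specific_activity(1.2), 40)
  # linear and invertible
  f <- c(0.1, 0.71, 2.5)
  expect_equal(specific_activity_to_flux(flux_to_specific_activity(f)), f)
  expect_equal(flux_to_specific_activity(2 * 0.78), 2 * 26)
  # other protein fractions rescale inversely
  expect_equal(flux_to_specific_activity(0.78, protein_fraction = 1), 13)
  expect_error(flux_to_specific_activity(-1), "non-negative")
  expect_error(flux_to_specific_activity(1, protein_fraction = 0), "0, 1")
})

test_that("yield slope is exact on noiseless series and windows matter", {
  s <- simulate_growth_series(5.2, 0.05, noise_sd = 0, n_points = 15, seed = 1)
  est <- suppressWarnings(estimate_yield(s))
  expect_equal(est$slope, 5.2, tolerance = 1e-9)
  expect_lt(est$se, 1e-9)

  # a nitrogen-limited plateau biases the full-window slope low
  sp <- simulate_growth_series(5.2, 0.05, noise_sd = 0, n_points = 24, seed = 1,
                               plateau_from = 0.5)
  full <- estimate_yield(sp)
  linear <- suppressWarnings(estimate_yield(sp, window = 1:12))
  expect_equal(linear$slope, 5.2, tolerance = 1e-6)
  expect_lt(full$slope, linear$slope)

  expect_error(estimate_yield(s, window = 1:2), "at least 3")
  flat <- s; flat$substrate_mmol <- 10
  expect_error(estimate_yield(flat), "slope undefined")
})

test_that("yield estimator is unbiased and well-calibrated under noise", {
  reps <- 300
  est <- vapply(seq_len(reps), function(i) {
    s <- simulate_growth_series(5.2, 0.05, noise_sd = 0.002, n_points = 20,
                                seed = 1000 + i)
    e <- estimate_yield(s)
    c(e$slope, e$se)
  }, numeric(2))
  mc_se <- stats::sd(est[1, ]) / sqrt(reps)
  expect_lt(abs(mean(est[1, ]) - 5.2), 3 * mc_se)         # unbiased
  covered <- mean(abs(est[1, ] - 5.2) <= 2 * est[2, ])
  expect_gte(covered, 0.9)                                # ~95% nominal
})

test_that("headspace helper follows the ideal gas law", {
  # 10% v/v in 100 ml at 25 C, 1 atm: n = PV/RT
  expect_equal(headspace_to_mmol(0.1, 100),
               0.1 * 0.1 / (0.082057 * 298.15) * 1000, tolerance = 1e-9)
  expect_equal(headspace_to_mmol(0, 100), 0)
})
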