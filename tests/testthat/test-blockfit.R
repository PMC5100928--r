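wt_truth <- block_model_params(0.3, 0.3, 0.5, z = 2, hill_n = 0.6)

test_that("the voltage-dependent dissociation constant evaluates in closed form", {
  expect_equal(kd_of_voltage(wt_truth, 0), 0.6)
  # delta = 0.5 makes the through-pathway term voltage independent
  p <- block_model_params(0.2, 0.4, 0.5, z = 2)
  v <- seq(-120, 120, 20)
  through <- kd_of_voltage(p, v) -
    0.2 * exp(0.5 * 2 * v / physical_constants()$RT_over_F_mV)
  expect_equal(through, rep(0.4, length(v)))
  # closed-form spot value at V = -RT/F
  rt_f <- physical_constants()$RT_over_F_mV
  expect_equal(kd_of_voltage(wt_truth, -rt_f), 0.3 * exp(-1) + 0.3)
  # bounded below by K_through as V -> -infinity when delta = 0.5
  expect_gte(kd_of_voltage(wt_truth, -1e4), 0.3)
  expect_equal(kd_of_voltage(wt_truth, -1e4), 0.3, tolerance = 1e-6)
})

test_that("the Hill unblocked fraction behaves at its anchor points", {
  expect_equal(hill_block_fraction(0, wt_truth, -80), 1)
  kd <- kd_of_voltage(wt_truth, -45)
  expect_equal(hill_block_fraction(kd, wt_truth, -45), 0.5)
  p <- block_model_params(0.3, 0.3, 0.5, z = 2, hill_n = 0.5)
  expect_equal(hill_block_fraction(4 * kd_of_voltage(p, 30), p, 30), 1 / 3)
})

test_that("noiseless block families are inverted exactly", {
  ds <- simulate_block_dataset(wt_truth, 5000, c(0.3, 1, 3, 10, 30))
  fit <- fit_block_model(ds, z = 2)
  expect_true(fit$converged)
  expect_equal(fit$params$K_out_mM, 0.3, tolerance = 1e-4)
  expect_equal(fit$params$K_through_mM, 0.3, tolerance = 1e-4)
  expect_equal(fit$params$delta, 0.5, tolerance = 1e-4)
  expect_equal(fit$params$hill_n, 0.6, tolerance = 1e-4)
  expect_equal(fit$KD0_mM, 0.6, tolerance = 1e-4)
})

test_that("the optimizer matches an exhaustive grid search on a small grid", {
  ds <- simulate_block_dataset(wt_truth, 5000, c(0.5, 2, 8),
                               voltages_mV = seq(-100, 60, 10))
  fit <- fit_block_model(ds, z = 2)
  grid <- grid_search_block(ds, z = 2,
                            K_grid = c(0.1, 0.2, 0.3, 0.45, 0.7),
                            delta_grid = seq(0.1, 0.9, 0.2),
                            n_grid = c(0.4, 0.6, 0.9, 1.3))
  # the optimizer must do at least as well as the best grid point, and the
  # grid optimum must sit at the truth (which the optimizer recovers)
  expect_lte(fit$rss, grid$sse + 1e-12)
  expect_equal(grid$K_out, 0.3)
  expect_equal(grid$K_through, 0.3)
  expect_equal(grid$delta, 0.5)
  expect_equal(grid$hill_n, 0.6)
})

test_that("degenerate block datasets are rejected with informative errors", {
  expect_error(fit_block_model(simulate_block_dataset(wt_truth, 5000, 0)),
               "under-determined")
  ds_narrow <- simulate_block_dataset(wt_truth, 5000, c(1, 10),
                                      voltages_mV = seq(-80, 80, 40))
  expect_error(fit_block_model(ds_narrow), "10 voltages")
})

test_that("noisy block families recover the generator truth within tolerance", {
  ds <- simulate_block_dataset(wt_truth, 5000, c(0.3, 1, 3, 10, 30),
                               noise_fraction = 0.02, seed = 21)
  fit <- fit_block_model(ds, z = 2)
  expect_equal(fit$KD0_mM, 0.6, tolerance = 0.15)
  expect_equal(fit$params$delta, 0.5, tolerance = 0.1 / 0.5)
})

test_that("parameter recovery is identifiable across stochastic replicates", {
  errs_kd <- errs_delta <- numeric(50)
  for (r in 1:50) {
    ds <- simulate_block_dataset(wt_truth, 5000, c(0.3, 1, 3, 10, 30),
                                 noise_fraction = 0.02, seed = 1000 + r)
    fit <- fit_block_model(ds, z = 2)
    errs_kd[r] <- abs(fit$KD0_mM - 0.6) / 0.6
    errs_delta[r] <- abs(fit$params$delta - 0.5)
  }
  expect_lte(stats::median(errs_kd), 0.10)
  expect_lte(stats::median(errs_delta), 0.05)
})

test_that("divalent block rectification deepens monotonically with concentration", {
  ratio <- vapply(c(0.5, 1, 2, 5, 10), function(cc) {
    d <- simulate_block_dataset(wt_truth, 5000, cc,
                                voltages_mV = seq(-100, 100, 5))
    abs(d$norm_current[d$voltage_mV == -80]) /
      abs(d$norm_current[d$voltage_mV == 80])
  }, numeric(1))
  expect_true(all(diff(ratio) < 0))
  expect_true(all(ratio < 1))
})

test_that("Hill dose-response fits recover exact curves and flag degenerate data", {
  conc <- c(0.05, 0.2, 0.5, 1, 3, 10, 50)
  frac <- 1 / (1 + (conc / 1)^0.54)
  fit <- fit_dose_response(conc, frac)
  expect_equal(fit$K_D, 1, tolerance = 1e-6)
  expect_equal(fit$hill_n, 0.54, tolerance = 1e-6)
  # the C = K_D anchor
  expect_equal(1 / (1 + (fit$K_D / fit$K_D)^fit$hill_n), 0.5)
  # all-unblocked data: K_D unbounded, flagged rather than fitted
  f2 <- fit_dose_response(conc, rep(1, length(conc)))
  expect_true(f2$flagged)
  expect_equal(f2$K_D, Inf)
  expect_error(fit_dose_response(c(1, 2), c(0.8, 0.6)), "at least 3")
  expect_warning(fit_dose_response(c(1, 2, 4, 8), c(0.9, 0.4, 0.8, 0.2)),
                 "non-monotone")
})
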