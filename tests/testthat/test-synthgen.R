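test_that("voltage protocols validate their invariants and map samples linearly", {
  p <- ramp_protocol()
  expect_equal(p$n_samples, 2000)
  v <- protocol_voltage(p)
  expect_equal(v[1], -100)
  expect_equal(v[length(v)], 100)
  expect_equal(diff(v), rep(200 / 1999, 1999))
  expect_equal(unique(protocol_voltage(hold_protocol(-60))), -60)
  expect_error(voltage_protocol(duration_s = 0), "duration")
  expect_error(voltage_protocol(sample_rate_Hz = 8000, filter_cutoff_Hz = 5000),
               "twice")
  # an anti-alias filter at Nyquist itself (the standard recording setup) is legal
  expect_silent(voltage_protocol(sample_rate_Hz = 10000, filter_cutoff_Hz = 5000))
})

test_that("an absorbing closed state yields an all-closed trajectory", {
  fx <- gating_fixture("still", 251, 170, open_rate_Hz = 0)
  tr <- simulate_gating(fx, hold_protocol(-60), seed = 1)
  expect_true(all(tr == "closed"))
})

test_that("gating matches its stationary distribution and dwell-time law", {
  fx <- gating_fixture("fast", 251, 170, open_rate_Hz = 100, close_rate_Hz = 100)
  p <- hold_protocol(-60, duration_s = 10)  # 1e5 samples
  tr <- simulate_gating(fx, p, seed = 11)
  frac <- mean(tr != "closed")
  expect_equal(frac, 0.5, tolerance = 0.04)  # |frac - 0.5| < 0.02 absolute
  # 3-sigma check at the effective number of independent gating cycles
  n_cycles <- 10 / (1 / 100 + 1 / 100)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_cycles))
  # mean open dwell ~ 1/close_rate over >= 1000 events
  r <- rle(as.character(tr) != "closed")
  open_runs <- r$lengths[r$values]
  open_runs <- open_runs[-c(1, length(open_runs))]  # drop edge-truncated dwells
  expect_gt(length(open_runs), 400)
  tr2 <- simulate_gating(fx, p, seed = 12)
  r2 <- rle(as.character(tr2) != "closed")
  open_runs <- c(open_runs, r2$lengths[r2$values])
  mean_dwell_s <- mean(open_runs) / p$sample_rate_Hz
  expect_equal(mean_dwell_s, 1 / 100, tolerance = 0.05)
})

test_that("sub-levels are assigned per opening with the fixture probability", {
  fx <- gating_fixture("mix", 251, 170, p_small = 0.3,
                       open_rate_Hz = 200, close_rate_Hz = 200)
  tr <- simulate_gating(fx, hold_protocol(-60, duration_s = 10), seed = 3)
  r <- rle(as.character(tr))
  openings <- r$values[r$values != "closed"]
  expect_gt(length(openings), 1000)
  p_hat <- mean(openings == "open_small")
  expect_lt(abs(p_hat - 0.3), 3 * sqrt(0.3 * 0.7 / length(openings)))
})

test_that("rendering converts states to currents with the pS*mV*1e-3 scaling", {
  p <- hold_protocol(-60, duration_s = 0.01)
  quiet <- gating_fixture("quiet", 251, 170, leak_pS = 0, noise_rms_pA = 1e-9)
  closed <- factor(rep("closed", p$n_samples),
                   levels = c("closed", "open_large", "open_small"))
  open_l <- factor(rep("open_large", p$n_samples),
                   levels = levels(closed))
  expect_lt(max(abs(render_sweep(closed, quiet, p, 1)$current_pA)), 1e-6)
  sw <- render_sweep(open_l, quiet, p, 1)
  expect_equal(mean(sw$current_pA), -15.06, tolerance = 1e-6)
  # linear in gamma and in driving force
  quiet2 <- gating_fixture("quiet2", 502, 340, leak_pS = 0, noise_rms_pA = 1e-9)
  expect_equal(mean(render_sweep(open_l, quiet2, p, 1)$current_pA),
               2 * mean(sw$current_pA), tolerance = 1e-6)
  p2 <- hold_protocol(-120, duration_s = 0.01)
  open_l2 <- factor(rep("open_large", p2$n_samples), levels = levels(closed))
  expect_equal(mean(render_sweep(open_l2, quiet, p2, 1)$current_pA),
               2 * mean(sw$current_pA), tolerance = 1e-6)
  expect_error(render_sweep(closed[-1], quiet, p, 1), "length")
})

test_that("noise is calibrated to the requested RMS and seeds are reproducible", {
  p <- hold_protocol(0, duration_s = 1)
  fx <- gating_fixture("noisy", 251, 170, open_rate_Hz = 0, leak_pS = 0,
                       noise_rms_pA = 1)
  ct <- make_control_sweep(fx, p, seed = 5)
  expect_equal(sqrt(mean(ct$current_pA^2)), 1, tolerance = 0.1)
  expect_identical(ct$current_pA,
                   make_control_sweep(fx, p, seed = 5)$current_pA)
  # a sub-Nyquist filter still yields the calibrated RMS
  p2 <- voltage_protocol("hold", hold_voltage_mV = 0, duration_s = 1,
                         sample_rate_Hz = 20000, filter_cutoff_Hz = 5000)
  ct2 <- make_control_sweep(fx, p2, seed = 5)
  expect_equal(sqrt(mean(ct2$current_pA^2)), 1, tolerance = 1e-9)
  # and shapes the spectrum: lag-1 autocorrelation of filtered noise is high
  expect_gt(stats::cor(ct2$current_pA[-1], ct2$current_pA[-length(ct2$current_pA)]),
            0.5)
})

test_that("control sweeps carry leak and differ between seeds only in noise", {
  p <- hold_protocol(100, duration_s = 0.5)
  fx <- gating_fixture("leaky", 251, 170, leak_pS = 50, noise_rms_pA = 1)
  c1 <- make_control_sweep(fx, p, seed = 1)
  c2 <- make_control_sweep(fx, p, seed = 2)
  n <- p$n_samples
  sem <- 1 / sqrt(n)
  expect_equal(mean(c1$current_pA), 5, tolerance = 3 * sem)
  expect_lt(abs(mean(c1$current_pA) - mean(c2$current_pA)),
            3 * sqrt(2) * sem)
})

test_that("the reversal potential is the unique zero crossing of the open trace", {
  p <- ramp_protocol()
  fx <- gating_fixture("rev", 251, 170, reversal_mV = 10, leak_pS = 0,
                       noise_rms_pA = 1e-9)
  open_l <- factor(rep("open_large", p$n_samples),
                   levels = c("closed", "open_large", "open_small"))
  sw <- render_sweep(open_l, fx, p, 1)
  v <- protocol_voltage(p)
  sgn <- sign(sw$current_pA)
  expect_true(all(sgn[v < 10 - 1e-6] == -1))
  expect_true(all(sgn[v > 10 + 1e-6] == 1))
})

test_that("the fixture registry exposes the packaged condition truths", {
  expect_equal(fixture_registry("WT-150")$gamma_large_pS, 251)
  expect_equal(fixture_registry("WT-150")$gamma_small_pS, 170)
  expect_equal(fixture_registry("E920A-150")$gamma_large_pS, 172)
  expect_equal(fixture_registry("WT-500")$gamma_large_pS, 345)
  ba <- fixture_registry("Ba-WT")
  expect_equal(ba$K_out_mM + ba$K_through_mM, 0.6)
  expect_equal(ba$delta, 0.5)
  expect_error(fixture_registry("WT-9000"), "unknown fixture")
})

test_that("block datasets are normalized, rectified by divalents, and validated", {
  truth <- fixture_registry("Ba-WT")
  ds0 <- simulate_block_dataset(truth, 5000, 0, voltages_mV = seq(-100, 100, 5))
  # C = 0: linear through the reversal potential
  fit <- stats::lm(norm_current ~ voltage_mV, data = ds0)
  expect_lt(max(abs(stats::residuals(fit))), 1e-12)
  ds <- simulate_block_dataset(truth, 5000, c(0.5, 2, 10),
                               voltages_mV = seq(-100, 100, 5),
                               noise_fraction = 0.05, seed = 7)
  v_norm <- attr(ds, "normalization_voltage_mV")
  for (cc in unique(ds$concentration_mM)) {
    expect_equal(ds$norm_current[ds$concentration_mM == cc &
                                   ds$voltage_mV == v_norm], 1)
  }
  # 2 mM divalent block produces outward rectification
  d2 <- simulate_block_dataset(truth, 5000, 2, voltages_mV = seq(-100, 100, 5))
  a <- abs(d2$norm_current[d2$voltage_mV == -80])
  b <- abs(d2$norm_current[d2$voltage_mV == 80])
  expect_lt(a / b, 1)
  expect_error(simulate_block_dataset(truth, 5000, numeric(0)),
               "at least one")
  expect_error(simulate_block_dataset(truth, 5000, c(2, 1)), "increasing")
})
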