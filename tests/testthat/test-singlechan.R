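test_that("leak subtraction is a pointwise difference and validates protocols", {
  p <- hold_protocol(-60, duration_s = 0.05)
  fx <- fixture_registry("WT-150")
  sw <- simulate_sweep(fx, p, seed = 1)
  expect_true(all(subtract_leak(sw, sw)$current_pA == 0))
  # removing leak leaves open-channel current only
  quiet <- gating_fixture("q", 251, 170, leak_pS = 50, noise_rms_pA = 1e-9)
  open_l <- factor(rep("open_large", p$n_samples),
                   levels = c("closed", "open_large", "open_small"))
  sw2 <- render_sweep(open_l, quiet, p, 2)
  ct2 <- make_control_sweep(quiet, p, 3)
  corr <- subtract_leak(sw2, ct2)
  expect_equal(mean(corr$current_pA), -15.06, tolerance = 1e-6)
  # protocol mismatch rejected
  p2 <- hold_protocol(-60, duration_s = 0.06)
  expect_error(subtract_leak(sw, make_control_sweep(fx, p2, 4)), "protocol")
})

test_that("event detection matches a brute-force per-sample scan", {
  set.seed(99)
  for (rep in 1:20) {
    n <- 400
    x <- stats::rnorm(n, sd = 2)
    # implant a few square events of random sign/length
    for (k in 1:3) {
      s <- sample(n - 40, 1)
      x[s:(s + sample(3:30, 1))] <- sample(c(-1, 1), 1) * stats::runif(1, 4, 20)
    }
    got <- detect_events(x, threshold_pA = 3, min_duration_s = 5e-4,
                         sample_rate_Hz = 10000)
    want <- brute_force_events(x, threshold_pA = 3, min_n = 5)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$amplitude_pA, want$amplitude_pA)
  }
  # boundary convention: |I| exactly at threshold is kept
  x <- c(rep(0, 10), rep(3, 10), rep(0, 10))
  expect_equal(nrow(detect_events(x, 3, sample_rate_Hz = 10000)), 1)
  expect_equal(nrow(detect_events(rep(2.9, 100), 3, sample_rate_Hz = 10000)), 0)
})

test_that("clean square pulses are idealized with their amplitude", {
  x <- c(rep(0, 100), rep(-15.06, 100), rep(0, 100))
  ev <- detect_events(x, sample_rate_Hz = 10000)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude_pA, -15.06, tolerance = 0.05 / 15.06)
  expect_equal(ev$n_samples, 100)
})

test_that("pure noise below threshold produces essentially no events", {
  fx <- gating_fixture("quiet", 251, 170, open_rate_Hz = 0, leak_pS = 0,
                       noise_rms_pA = 1)
  p <- hold_protocol(0, duration_s = 2)
  ev <- detect_events(make_control_sweep(fx, p, seed = 8))
  expect_equal(nrow(ev), 0)
})

test_that("amplitude mixtures resolve one or two open levels by BIC", {
  p <- hold_protocol(-60, duration_s = 0.3)
  # single level: openings forced large -> one component selected
  ens1 <- make_ensemble("WT-150", p, n = 40, base_seed = 200,
                        large_only = TRUE)
  f1 <- fit_amplitude_states(pool_points(ens1), at_voltage_mV = -60)
  expect_equal(f1$n_components, 1)
  expect_equal(f1$conductances_pS[1], 251, tolerance = 10 / 251)
  # two levels: WT-150 mixture, conductance ratio ~170/251
  ens2 <- make_ensemble("WT-150", p, n = 80, base_seed = 300)
  f2 <- fit_amplitude_states(pool_points(ens2), at_voltage_mV = -60)
  expect_equal(f2$n_components, 2)
  expect_equal(f2$ratio_small_large, 170 / 251, tolerance = 0.05 / 0.677)
  expect_equal(sum(f2$weights), 1, tolerance = 1e-8)
  # generator means recovered within 2 SE plus a 0.1 pA resolution floor
  # (sub-resolution closed gaps inside merged events bias points slightly)
  n_large <- round(f2$weights[1] * f2$n_events)
  se_large <- f2$widths_pA[1] / sqrt(n_large)
  expect_lt(abs(abs(f2$means_pA[1]) - 15.06), 2 * se_large + 0.1)
  # per-event means remain a valid input for long, well-separated events
  f3 <- fit_amplitude_states(pool_events(ens2), at_voltage_mV = -60)
  expect_equal(f3$conductances_pS[1], 251, tolerance = 10 / 251)
})

test_that("degenerate and undersized amplitude samples are handled", {
  f <- fit_amplitude_states(rep(-15.06, 100), at_voltage_mV = -60)
  expect_equal(f$n_components, 1)
  expect_gte(min(f$widths_pA), 0.05)
  expect_equal(f$conductances_pS[1], 251, tolerance = 1e-6)
  expect_error(fit_amplitude_states(rnorm(10), at_voltage_mV = -60),
               "too few events")
})

test_that("averaged open-channel I-V reproduces an ohmic channel with a gap", {
  p <- ramp_protocol()
  ohm <- gating_fixture("ohm", 200, 100, p_small = 0, leak_pS = 0,
                        noise_rms_pA = 1e-9, open_rate_Hz = 200,
                        close_rate_Hz = 50)
  ens <- make_ensemble(ohm, p, n = 20, base_seed = 400)
  iv <- average_open_iv(ens$sweeps, ens$controls)
  # populated bins lie on I = 0.2 V outside the noise gap
  ok <- iv$n > 0
  expect_true(any(ok))
  expect_lt(max(abs(iv$mean_current_pA[ok] - 0.2 * iv$voltage_mV[ok])), 0.2)
  # gap invariant: bins with |0.2 V| < 3 pA (|V| < 15 mV) are empty
  gap <- abs(iv$voltage_mV) < 15 - 2.5
  expect_true(all(iv$n[gap] == 0))
  # no openings -> all bins empty
  still <- gating_fixture("still", 200, 100, open_rate_Hz = 0, leak_pS = 0,
                          noise_rms_pA = 1e-9)
  ens0 <- make_ensemble(still, p, n = 3, base_seed = 500)
  iv0 <- average_open_iv(ens0$sweeps, ens0$controls)
  expect_true(all(iv0$n == 0))
  expect_error(average_open_iv(list(simulate_sweep(ohm, hold_protocol(-60), 1)),
                               list(make_control_sweep(ohm, hold_protocol(-60), 2))),
               "ramp")
})

test_that("slope conductances recover an exact line and flag sparse branches", {
  p <- ramp_protocol()
  ohm <- gating_fixture("ohm", 200, 100, p_small = 0, leak_pS = 0,
                        noise_rms_pA = 1e-9, open_rate_Hz = 1e9,
                        close_rate_Hz = 1e-9)
  open_l <- factor(rep("open_large", p$n_samples),
                   levels = c("closed", "open_large", "open_small"))
  sw <- render_sweep(open_l, ohm, p, 1)
  ct <- make_control_sweep(ohm, p, 2)
  iv <- average_open_iv(list(sw), list(ct))
  est <- slope_conductance(iv)
  expect_equal(est$negative$conductance_pS, 200, tolerance = 1e-3)
  expect_equal(est$positive$conductance_pS, 200, tolerance = 1e-3)
  expect_lt(est$negative$se_pS, 0.5)
  # a branch with too few populated bins is reported absent
  iv_half <- iv[iv$voltage_mV > -10, ]
  class(iv_half) <- class(iv)
  est2 <- slope_conductance(iv_half)
  expect_null(est2$negative)
  expect_false(is.null(est2$positive))
})

test_that("conductance estimates are invariant to pure leak", {
  p <- ramp_protocol()
  base <- gating_fixture("nl", 200, 100, p_small = 0, leak_pS = 0,
                         noise_rms_pA = 1e-9, open_rate_Hz = 100,
                         close_rate_Hz = 50)
  leaky <- gating_fixture("wl", 200, 100, p_small = 0, leak_pS = 80,
                          noise_rms_pA = 1e-9, open_rate_Hz = 100,
                          close_rate_Hz = 50)
  # same gating seeds, same noise seeds: only the leak term differs
  ens_a <- make_ensemble(base, p, n = 10, base_seed = 600)
  ens_b <- make_ensemble(leaky, p, n = 10, base_seed = 600)
  sa <- slope_conductance(average_open_iv(ens_a$sweeps, ens_a$controls))
  sb <- slope_conductance(average_open_iv(ens_b$sweeps, ens_b$controls))
  expect_equal(sa$negative$conductance_pS, sb$negative$conductance_pS,
               tolerance = 1e-6)
  expect_equal(sa$positive$conductance_pS, sb$positive$conductance_pS,
               tolerance = 1e-6)
})

test_that("the gap-clearance helper scales inversely with conductance", {
  expect_equal(gap_clear_voltage(200, 3, 0, k = 0), 15)
  expect_equal(gap_clear_voltage(100, 3, 0, k = 0), 30)
  expect_gt(gap_clear_voltage(200, 3, sqrt(2)), 15)
})
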