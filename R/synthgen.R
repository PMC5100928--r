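#' Simulate two-state channel gating on a protocol's sample grid
#'
#' Gating is a continuous-time Markov chain alternating between closed and
#' open, with exponential dwell times (rates `open_rate_Hz`, from closed to
#' open, and `close_rate_Hz` back). Each opening independently enters the
#' smaller conductance level with probability `p_small`, otherwise the larger
#' level. The trajectory is sampled at the protocol grid; the initial state
#' is drawn from the stationary distribution so long traces are unbiased.
#'
#' @param fixture A [gating_fixture()].
#' @param protocol A [voltage_protocol()].
#' @param seed Integer seed; the same seed reproduces the same trajectory.
#' @return A factor vector of length `protocol$n_samples` with levels
#'   `closed`, `open_large`, `open_small`.
#' @examples
#' fx <- fixture_registry("WT-150")
#' table(simulate_gating(fx, hold_protocol(-60), seed = 1))
#' @export
simulate_gating <- function(fixture, protocol, seed) {
  stopifnot(inherits(fixture, "gating_fixture"),
            inherits(protocol, "voltage_protocol"))
  if (fixture$open_rate_Hz < 0 || fixture$close_rate_Hz < 0) {
    stop("gating rates must be non-negative")
  }
  n <- protocol$n_samples
  lv <- c("closed", "open_large", "open_small")
  if (fixture$open_rate_Hz == 0) {
    return(factor(rep("closed", n), levels = lv))
  }
  dur <- protocol$duration_s
  with_seed(seed, {
    p_open <- fixture$open_rate_Hz /
      (fixture$open_rate_Hz + fixture$close_rate_Hz)
    open_now <- stats::runif(1) < p_open
    # draw alternating dwells until the sweep is covered
    t_edge <- numeric(0)   # state-change times
    states <- logical(0)   # state *before* each edge
    t <- 0
    first_open <- open_now
    while (t < dur) {
      rate <- if (open_now) fixture$close_rate_Hz else fixture$open_rate_Hz
      dwell <- stats::rexp(1, rate)
      t <- t + dwell
      t_edge <- c(t_edge, t)
      states <- c(states, open_now)
      open_now <- !open_now
    }
    tt <- (seq_len(n) - 1) / protocol$sample_rate_Hz
    seg <- findInterval(tt, t_edge, left.open = TRUE) + 1
    is_open <- states[seg]
    # per-opening sub-level assignment
    open_seg_ids <- which(states)
    sub_small <- stats::runif(length(open_seg_ids)) < fixture$p_small
    small_by_seg <- rep(FALSE, length(states))
    small_by_seg[open_seg_ids] <- sub_small
    out <- ifelse(!is_open, "closed",
                  ifelse(small_by_seg[seg], "open_small", "open_large"))
    factor(out, levels = lv)
  })
}

# 4-pole low-pass Bessel filter, digitized by the bilinear transform.
# Analog prototype poles (normalized so the -3 dB point is at omega = 1):
# -0.6572 +/- 0.8302i, -0.9047 +/- 0.2709i. Returns an Arma filter, or NULL
# when the cutoff sits at (or above) Nyquist, where the digital
# approximation degenerates to the identity.
bessel4_lowpass <- function(cutoff_Hz, sample_rate_Hz) {
  if (cutoff_Hz >= 0.5 * sample_rate_Hz * 0.999) return(NULL)
  p <- c(complex(real = -0.65721173, imaginary = 0.83016565),
         complex(real = -0.65721173, imaginary = -0.83016565),
         complex(real = -0.90476063, imaginary = 0.27091873),
         complex(real = -0.90476063, imaginary = -0.27091873))
  # prewarp so the digital -3 dB point lands on cutoff_Hz
  wc <- 2 * sample_rate_Hz * tan(pi * cutoff_Hz / sample_rate_Hz)
  p <- p * wc
  g <- Re(prod(-p))   # unity DC gain
  signal::bilinear(Sz = numeric(0), Sp = p, Sg = g, T = 1 / sample_rate_Hz)
}

# Filtered Gaussian noise calibrated to a target RMS after filtering.
filtered_noise <- function(n, rms_pA, cutoff_Hz, sample_rate_Hz) {
  x <- stats::rnorm(n)
  flt <- bessel4_lowpass(cutoff_Hz, sample_rate_Hz)
  if (!is.null(flt)) {
    x <- as.numeric(signal::filter(flt, x))
  }
  x * rms_pA / sqrt(mean(x^2))
}

# Large-level conductance at each sample, honouring branch-specific slopes
# for rectifying fixtures rendered under ramp protocols.
level_conductance <- function(fixture, protocol, voltage_mV) {
  g_large <- rep(fixture$gamma_large_pS, length(voltage_mV))
  if (!is.null(fixture$branch_conductances) && protocol$kind == "ramp") {
    neg <- voltage_mV < fixture$reversal_mV
    g_large[neg] <- fixture$branch_conductances[["negative"]]
    g_large[!neg] <- fixture$branch_conductances[["positive"]]
  }
  g_large
}

#' Render a gating trajectory into a current sweep
#'
#' Converts per-sample gating states into a recorded current trace:
#' \deqn{I = \gamma(state)\,(V - V_{rev})\times 10^{-3}
#'          + g_{leak}\,V \times 10^{-3} + noise}
#' (pS x mV x 1e-3 = pA; inward current is negative). The recording noise is
#' white Gaussian shaped by a 4-pole low-pass Bessel approximation of the
#' recording filter and calibrated to `noise_rms_pA` after filtering. For
#' rectifying fixtures rendered under ramp protocols, the large-level
#' conductance takes the branch value for the sign of (V - V_rev) and the
#' small level is scaled proportionally.
#'
#' @param trajectory Factor from [simulate_gating()] (levels `closed`,
#'   `open_large`, `open_small`), matching the protocol grid.
#' @param fixture A [gating_fixture()].
#' @param protocol A [voltage_protocol()].
#' @param seed Integer seed for the noise stream.
#' @param blocker_mM Blocker concentration metadata carried on the sweep.
#' @return An object of class `sweep`: list with `current_pA`, `protocol`,
#'   `condition`, `blocker_mM`, `seed`.
#' @export
render_sweep <- function(trajectory, fixture, protocol, seed,
                         blocker_mM = 0) {
  stopifnot(inherits(fixture, "gating_fixture"),
            inherits(protocol, "voltage_protocol"))
  if (length(trajectory) != protocol$n_samples) {
    stop("trajectory length does not match the protocol sample grid")
  }
  v <- protocol_voltage(protocol)
  g_large <- level_conductance(fixture, protocol, v)
  g_small <- g_large * fixture$gamma_small_pS / fixture$gamma_large_pS
  gamma <- numeric(length(v))
  gamma[trajectory == "open_large"] <- g_large[trajectory == "open_large"]
  gamma[trajectory == "open_small"] <- g_small[trajectory == "open_small"]
  base <- gamma * (v - fixture$reversal_mV) * 1e-3 +
    fixture$leak_pS * v * 1e-3
  noise <- with_seed(seed, filtered_noise(length(v), fixture$noise_rms_pA,
                                          protocol$filter_cutoff_Hz,
                                          protocol$sample_rate_Hz))
  structure(list(current_pA = base + noise,
                 protocol = protocol,
                 condition = fixture$name,
                 blocker_mM = blocker_mM,
                 seed = seed),
            class = "sweep")
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf("sweep: condition '%s', %d samples, seed %s\n",
              x$condition, length(x$current_pA), format(x$seed)))
  invisible(x)
}

#' Simulate a control sweep (leak and noise only)
#'
#' The control trace for leak subtraction is a sweep in which the channel
#' never opens: identical leak and noise statistics, zero open-channel
#' current.
#'
#' @inheritParams render_sweep
#' @return A `sweep` object.
#' @export
make_control_sweep <- function(fixture, protocol, seed) {
  closed <- factor(rep("closed", protocol$n_samples),
                   levels = c("closed", "open_large", "open_small"))
  render_sweep(closed, fixture, protocol, seed)
}

#' Simulate one single-channel sweep (gating plus rendering)
#'
#' Convenience wrapper: draws a gating trajectory and renders it. Gating and
#' noise use decorrelated streams derived from `seed`.
#'
#' @inheritParams render_sweep
#' @return A `sweep` object.
#' @export
simulate_sweep <- function(fixture, protocol, seed, blocker_mM = 0) {
  traj <- simulate_gating(fixture, protocol, seed)
  render_sweep(traj, fixture, protocol, seed + 1000003L, blocker_mM = blocker_mM)
}

#' Simulate a multi-concentration whole-cell block dataset
#'
#' Whole-cell current families in increasing blocker concentration, as
#' recorded with voltage ramps. At each voltage
#' \deqn{I(V, C) = g\,(V - V_{rev})\,u(V, C)}
#' where `u` is the unblocked fraction from [hill_block_fraction()] with the
#' voltage-dependent dissociation constant of [kd_of_voltage()].
#' Multiplicative lognormal noise of coefficient of variation
#' `noise_fraction` is applied, and every curve is normalized to its value at
#' the highest voltage.
#'
#' @param params A [block_model_params()] truth.
#' @param unblocked_conductance_pS Whole-cell slope conductance without
#'   blocker (cancels under normalization).
#' @param concentrations_mM Increasing blocker concentrations (mM), >= 0.
#' @param voltages_mV Voltage grid (mV); default -110..+70 mV in 2 mV steps.
#' @param noise_fraction Coefficient of variation of multiplicative lognormal
#'   noise (0 for noiseless data).
#' @param seed Integer seed (needed when `noise_fraction > 0`).
#' @param reversal_mV Reversal potential.
#' @return An object of class `block_dataset`: data frame with columns
#'   `concentration_mM`, `voltage_mV`, `norm_current`, plus attributes
#'   `normalization_voltage_mV`, `reversal_mV`.
#' @examples
#' ds <- simulate_block_dataset(fixture_registry("Ba-WT"), 5000,
#'                              c(0.3, 1, 3, 10, 30), seed = 1)
#' @export
simulate_block_dataset <- function(params, unblocked_conductance_pS,
                                   concentrations_mM,
                                   voltages_mV = seq(-110, 70, by = 2),
                                   noise_fraction = 0, seed = 1,
                                   reversal_mV = 0) {
  stopifnot(inherits(params, "block_model_params"),
            noise_fraction >= 0, unblocked_conductance_pS > 0)
  if (length(concentrations_mM) == 0) {
    stop("at least one blocker concentration is required")
  }
  if (any(concentrations_mM < 0) ||
      is.unsorted(concentrations_mM, strictly = TRUE)) {
    stop("concentrations must be strictly increasing and non-negative")
  }
  v_norm <- max(voltages_mV)
  sdlog <- sqrt(log(1 + noise_fraction^2))
  rows <- with_seed(seed, {
    do.call(rbind, lapply(concentrations_mM, function(cc) {
      u <- hill_block_fraction(cc, params, voltages_mV)
      i <- unblocked_conductance_pS * (voltages_mV - reversal_mV) * 1e-3 * u
      if (noise_fraction > 0) {
        i <- i * stats::rlnorm(length(i), meanlog = -sdlog^2 / 2,
                               sdlog = sdlog)
      }
      data.frame(concentration_mM = cc, voltage_mV = voltages_mV,
                 norm_current = i / i[which.max(voltages_mV)])
    }))
  })
  structure(rows,
            normalization_voltage_mV = v_norm,
            reversal_mV = reversal_mV,
            class = c("block_dataset", "data.frame"))
}
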