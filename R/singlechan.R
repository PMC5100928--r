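#' Leak subtraction of a single-channel sweep
#'
#' Subtracts a control trace (a sweep with no channel openings, recorded
#' under the same protocol) from an experimental sweep, removing seal leak
#' and capacitive components and leaving open-channel current plus noise.
#'
#' @param sweep,control `sweep` objects sharing the same protocol.
#' @return A `sweep` with the pointwise current difference.
#' @export
subtract_leak <- function(sweep, control) {
  stopifnot(inherits(sweep, "sweep"), inherits(control, "sweep"))
  if (!protocols_equal(sweep$protocol, control$protocol) ||
      length(sweep$current_pA) != length(control$current_pA)) {
    stop("sweep and control must share the same protocol and length")
  }
  out <- sweep
  out$current_pA <- sweep$current_pA - control$current_pA
  out
}

#' Threshold-run event detection
#'
#' Idealizes a (leak-subtracted) trace into channel-opening events: maximal
#' runs of consecutive samples with `|I| >= threshold_pA` lasting at least
#' `min_duration_s`. Points below the threshold are treated as noise and
#' removed, so a 3 pA threshold with ~1 pA RMS noise keeps essentially no
#' false events. The event amplitude is the mean current over the run.
#'
#' @param x A `sweep` object, or a numeric current vector (pA).
#' @param threshold_pA Detection threshold in pA (> 0); samples with
#'   `|I| >= threshold_pA` are retained (strictly smaller magnitudes are
#'   discarded).
#' @param min_duration_s Minimum event duration in seconds (default 0.5 ms,
#'   about the risetime of a 5 kHz recording filter).
#' @param sample_rate_Hz Required when `x` is a bare numeric vector.
#' @param voltage_mV Optional per-sample voltage; taken from the sweep's
#'   protocol when available.
#' @return A data frame of class `event_table`: columns `start`, `end`
#'   (sample indices, inclusive), `n_samples`, `amplitude_pA` (mean over the
#'   run) and `voltage_mV` (mean voltage over the run, NA if unknown).
#' @examples
#' pulse <- c(rep(0, 50), rep(-15.06, 100), rep(0, 50))
#' detect_events(pulse, sample_rate_Hz = 10000)
#' @export
detect_events <- function(x, threshold_pA = 3, min_duration_s = 5e-4,
                          sample_rate_Hz = NULL, voltage_mV = NULL) {
  stopifnot(threshold_pA > 0, min_duration_s >= 0)
  if (inherits(x, "sweep")) {
    if (is.null(voltage_mV)) voltage_mV <- protocol_voltage(x$protocol)
    sample_rate_Hz <- x$protocol$sample_rate_Hz
    x <- x$current_pA
  }
  if (is.null(sample_rate_Hz)) {
    stop("sample_rate_Hz is required when x is a numeric vector")
  }
  min_n <- max(1, ceiling(min_duration_s * sample_rate_Hz))
  above <- abs(x) >= threshold_pA
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_n
  starts <- starts[keep]; ends <- ends[keep]
  amp <- vapply(seq_along(starts),
                function(i) mean(x[starts[i]:ends[i]]), numeric(1))
  volt <- if (is.null(voltage_mV)) {
    rep(NA_real_, length(starts))
  } else {
    vapply(seq_along(starts),
           function(i) mean(voltage_mV[starts[i]:ends[i]]), numeric(1))
  }
  structure(data.frame(start = starts, end = ends,
                       n_samples = ends - starts + 1,
                       amplitude_pA = amp, voltage_mV = volt),
            class = c("event_table", "data.frame"))
}

#' Current points belonging to detected events
#'
#' Pools the raw current samples inside detected events, the data underlying
#' a per-point amplitude histogram. Unlike per-event mean amplitudes, point
#' amplitudes have homogeneous (recording-noise) variance, so Gaussian
#' mixtures on them resolve conductance levels cleanly.
#'
#' @param x The trace the events were detected on: a `sweep` or numeric
#'   vector (pA).
#' @param events The matching `event_table` from [detect_events()].
#' @return Numeric vector of current samples (pA) inside events.
#' @export
open_point_amplitudes <- function(x, events) {
  if (inherits(x, "sweep")) x <- x$current_pA
  if (nrow(events) == 0) return(numeric(0))
  unlist(mapply(function(s, e) x[s:e], events$start, events$end,
                SIMPLIFY = FALSE), use.names = FALSE)
}

#' Gaussian-mixture fit of amplitude histograms
#'
#' Fits one- and two-component Gaussian mixtures to open-channel amplitudes
#' at a fixed voltage and selects between them by BIC, the standard way of
#' resolving a main open level and a sub-conductance level in amplitude
#' histograms. Amplitudes are ideally per-point open-channel currents (see
#' [open_point_amplitudes()]); per-event means also work when events are
#' long. Components are reported largest-magnitude first and converted to
#' conductances via `gamma = |mean| / |V - V_rev| * 1000` (pS). Samples
#' larger than `max_points` are thinned deterministically before fitting.
#'
#' @param events An `event_table` (its mean amplitudes are used) or a numeric
#'   amplitude vector (pA), typically from [open_point_amplitudes()].
#' @param at_voltage_mV Voltage at which the events were recorded (mV).
#' @param reversal_mV Reversal potential (mV).
#' Two components are only reported when their means are separated beyond the
#' noise resolution (`min_separation_sd` times the wider component); closer
#' pairs are collapsed to a single level, since sub-states within the noise
#' width are not resolvable open levels.
#'
#' @param min_events Minimum number of amplitude observations required.
#' @param max_points Thinning cap on the number of observations fitted.
#' @param min_separation_sd Minimum mean separation, in units of the wider
#'   component SD, for two levels to count as resolved.
#' @return An object of class `amplitude_fit`: list with `means_pA`,
#'   `widths_pA`, `weights` (all ordered large level first),
#'   `conductances_pS`, `ratio_small_large` (NA for one component),
#'   `n_components`, `n_events`, `bic`.
#' @export
fit_amplitude_states <- function(events, at_voltage_mV, reversal_mV = 0,
                                 min_events = 50, max_points = 50000,
                                 min_separation_sd = 2) {
  amps <- if (is.data.frame(events)) events$amplitude_pA else as.numeric(events)
  if (length(amps) < min_events) {
    stop(sprintf("too few events (%d < %d) for amplitude fitting",
                 length(amps), min_events))
  }
  if (length(amps) > max_points) {
    amps <- amps[round(seq(1, length(amps), length.out = max_points))]
  }
  dv <- abs(at_voltage_mV - reversal_mV)
  stopifnot(dv > 0)
  floor_sd <- 0.05   # pA resolution floor for degenerate samples
  if (stats::sd(amps) < 1e-9) {
    fit <- list(means = mean(amps), sds = floor_sd, weights = 1,
                G = 1L, bic = NA_real_)
  } else {
    mc <- tryCatch({
      b <- mclust::mclustBIC(amps, G = 1:2, modelNames = "V",
                             verbose = FALSE)
      mclust::summaryMclustBIC(b, amps)
    }, error = function(e) NULL)
    if (is.null(mc) || length(mc$parameters$mean) == 0) {
      fit <- list(means = mean(amps), sds = max(stats::sd(amps), floor_sd),
                  weights = 1, G = 1L, bic = NA_real_)
    } else {
      fit <- list(means = as.numeric(mc$parameters$mean),
                  sds = sqrt(pmax(as.numeric(mc$parameters$variance$sigmasq),
                                  floor_sd^2)),
                  weights = as.numeric(mc$parameters$pro),
                  G = mc$G, bic = as.numeric(mc$bic))
      if (length(fit$sds) == 1) fit$sds <- rep(fit$sds, fit$G)
    }
  }
  if (fit$G == 2 &&
      abs(diff(fit$means)) < min_separation_sd * max(fit$sds)) {
    # unresolvable split: collapse to the pooled single level
    mu <- sum(fit$weights * fit$means)
    sd_pool <- sqrt(sum(fit$weights * (fit$sds^2 + (fit$means - mu)^2)))
    fit <- list(means = mu, sds = max(sd_pool, floor_sd), weights = 1,
                G = 1L, bic = fit$bic)
  }
  ord <- order(abs(fit$means), decreasing = TRUE)
  means <- fit$means[ord]; sds <- fit$sds[ord]; w <- fit$weights[ord]
  cond <- abs(means) / dv * 1000
  structure(list(means_pA = means, widths_pA = sds, weights = w,
                 conductances_pS = cond,
                 ratio_small_large = if (length(cond) == 2) {
                   cond[2] / cond[1]
                 } else NA_real_,
                 n_components = length(means),
                 n_events = length(amps),
                 bic = fit$bic),
            class = "amplitude_fit")
}

#' @export
print.amplitude_fit <- function(x, ...) {
  cat(sprintf("amplitude fit: %d component(s) over %d events\n",
              x$n_components, x$n_events))
  for (i in seq_len(x$n_components)) {
    cat(sprintf("  level %d: %.2f pA (sd %.2f, weight %.2f) -> %.1f pS\n",
                i, x$means_pA[i], x$widths_pA[i], x$weights[i],
                x$conductances_pS[i]))
  }
  if (!is.na(x$ratio_small_large)) {
    cat(sprintf("  small/large conductance ratio: %.3f\n",
                x$ratio_small_large))
  }
  invisible(x)
}

#' Averaged open-channel current-voltage relation from ramp sweeps
#'
#' Reproduces the single-channel I-V procedure: each sweep is leak-subtracted
#' against its control, samples within the noise band (`|I| < threshold_pA`)
#' are discarded, open-channel events are identified as supra-threshold runs
#' of at least `min_duration_s` (which removes isolated noise excursions),
#' and the event samples from all sweeps are averaged in voltage bins. The
#' discarded band produces the characteristic gap around the reversal
#' potential.
#'
#' @param sweeps,controls Lists of `sweep` objects (ramp protocol), paired by
#'   position.
#' @param threshold_pA Noise threshold in pA.
#' @param min_duration_s Minimum event duration (s); see [detect_events()].
#' @param bin_mV Voltage bin width (mV).
#' @return A data frame of class `iv_curve`: columns `voltage_mV` (bin
#'   center), `mean_current_pA`, `sd_pA`, `n`. Bins with no retained samples
#'   have `n = 0` and NA means.
#' @export
average_open_iv <- function(sweeps, controls, threshold_pA = 3,
                            min_duration_s = 5e-4, bin_mV = 5) {
  stopifnot(length(sweeps) == length(controls), length(sweeps) >= 1)
  if (sweeps[[1]]$protocol$kind != "ramp") {
    stop("open-channel I-V averaging requires ramp sweeps")
  }
  v <- protocol_voltage(sweeps[[1]]$protocol)
  all_v <- numeric(0); all_i <- numeric(0)
  for (k in seq_along(sweeps)) {
    corr <- subtract_leak(sweeps[[k]], controls[[k]])
    ev <- detect_events(corr, threshold_pA = threshold_pA,
                        min_duration_s = min_duration_s)
    if (nrow(ev) == 0) next
    idx <- unlist(mapply(function(s, e) s:e, ev$start, ev$end,
                         SIMPLIFY = FALSE), use.names = FALSE)
    all_v <- c(all_v, v[idx])
    all_i <- c(all_i, corr$current_pA[idx])
  }
  lo <- floor(min(v) / bin_mV) * bin_mV
  hi <- ceiling(max(v) / bin_mV) * bin_mV
  breaks <- seq(lo, hi, by = bin_mV)
  centers <- breaks[-1] - bin_mV / 2
  idx <- findInterval(all_v, breaks, rightmost.closed = TRUE)
  mean_i <- sd_i <- rep(NA_real_, length(centers))
  n <- integer(length(centers))
  if (length(all_v)) {
    tab <- tapply(all_i, factor(idx, levels = seq_along(centers)),
                  function(z) c(mean(z), stats::sd(z), length(z)))
    for (b in seq_along(centers)) {
      if (!is.null(tab[[b]])) {
        mean_i[b] <- tab[[b]][1]; sd_i[b] <- tab[[b]][2]
        n[b] <- tab[[b]][3]
      }
    }
  }
  structure(data.frame(voltage_mV = centers, mean_current_pA = mean_i,
                       sd_pA = sd_i, n = n),
            threshold_pA = threshold_pA, bin_mV = bin_mV,
            class = c("iv_curve", "data.frame"))
}

#' Fixture variant with large-level openings only
#'
#' Returns a copy of a gating fixture whose openings all enter the larger
#' conductance level (`p_small = 0`). Averaged open-channel I-V analyses
#' measure only the larger open state, so ramp ensembles destined for slope
#' conductance estimation are simulated under this variant.
#'
#' @param fixture A [gating_fixture()].
#' @return The modified `gating_fixture`.
#' @export
only_large_openings <- function(fixture) {
  stopifnot(inherits(fixture, "gating_fixture"))
  fixture$p_small <- 0
  fixture
}

#' Voltage needed to clear the noise-censoring band of an open level
#'
#' Samples are retained only when `|I| >= threshold_pA`, so near the reversal
#' potential an open level of conductance `gamma_pS` is partially censored
#' and binned means are biased. The bias is negligible once the expected
#' open-channel current exceeds the threshold by a margin of recording noise;
#' this helper returns that clearance voltage,
#' `(threshold + k sigma) / gamma`, used to place branch fit windows.
#'
#' @param gamma_pS Smallest open-level conductance entering the average (pS).
#' @param threshold_pA Noise threshold (pA).
#' @param noise_sd_pA Per-sample noise SD of the leak-subtracted trace (pA);
#'   sqrt(2) x the sweep RMS when a control is subtracted.
#' @param k Margin in noise SDs (default 2).
#' @return Clearance voltage in mV.
#' @export
gap_clear_voltage <- function(gamma_pS, threshold_pA = 3,
                              noise_sd_pA = sqrt(2), k = 2) {
  stopifnot(gamma_pS > 0)
  (threshold_pA + k * noise_sd_pA) / gamma_pS * 1000
}

#' Branch slope conductances from an averaged I-V curve
#'
#' Ordinary least-squares slopes of the averaged open-channel I-V relation,
#' fitted separately on the negative (`V < -v_min_mV`) and positive
#' (`V > v_min_mV`) branches, clear of the noise gap around the reversal
#' potential. Slopes in pA/mV are reported as pS.
#'
#' @param iv An `iv_curve` from [average_open_iv()].
#' @param v_min_mV Exclusion half-width around 0 mV (default 20 mV).
#' @param min_bins Minimum populated bins per branch.
#' @return An object of class `conductance_estimate`: list with `negative`
#'   and `positive` branches, each `NULL` (insufficient bins) or a list with
#'   `conductance_pS`, `se_pS`, `n_bins`, `v_range_mV`.
#' @export
slope_conductance <- function(iv, v_min_mV = 20, min_bins = 5) {
  stopifnot(inherits(iv, "iv_curve"))
  fit_branch <- function(rows) {
    if (sum(rows) < min_bins) return(NULL)
    d <- iv[rows, ]
    m <- stats::lm(mean_current_pA ~ voltage_mV, data = d)
    co <- summary(m)$coefficients
    list(conductance_pS = unname(co["voltage_mV", "Estimate"]) * 1000,
         se_pS = unname(co["voltage_mV", "Std. Error"]) * 1000,
         n_bins = nrow(d),
         v_range_mV = range(d$voltage_mV))
  }
  ok <- iv$n > 0 & !is.na(iv$mean_current_pA)
  structure(list(
    negative = fit_branch(ok & iv$voltage_mV < -v_min_mV),
    positive = fit_branch(ok & iv$voltage_mV > v_min_mV)),
    class = "conductance_estimate")
}

#' @export
print.conductance_estimate <- function(x, ...) {
  for (br in c("negative", "positive")) {
    b <- x[[br]]
    if (is.null(b)) {
      cat(sprintf("%s branch: insufficient bins\n", br))
    } else {
      cat(sprintf("%s branch: %.1f pS (SE %.1f, %d bins, %g to %g mV)\n",
                  br, b$conductance_pS, b$se_pS, b$n_bins,
                  b$v_range_mV[1], b$v_range_mV[2]))
    }
  }
  invisible(x)
}
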