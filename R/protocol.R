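#' Voltage-clamp stimulus protocol
#'
#' Describes one episodic stimulus: either a constant holding potential or a
#' linear voltage ramp, together with the acquisition settings (sampling rate
#' and low-pass filter cutoff). The standard single-channel ramp runs from
#' -100 to +100 mV in 200 ms, sampled at 10 kHz through a 5 kHz Bessel
#' filter.
#'
#' @param kind "hold" or "ramp".
#' @param hold_voltage_mV Holding potential (mV), used when `kind = "hold"`.
#' @param ramp_start_mV,ramp_end_mV Ramp endpoints (mV); the voltage is
#'   mapped linearly over the sample grid.
#' @param duration_s Sweep duration in seconds.
#' @param sample_rate_Hz Sampling rate (Hz).
#' @param filter_cutoff_Hz Low-pass filter cutoff (Hz); must not exceed the
#'   Nyquist frequency. An analog anti-alias filter may legitimately sit at
#'   Nyquist itself, so equality is allowed.
#' @return An object of class `voltage_protocol`.
#' @examples
#' ramp_protocol()
#' hold_protocol(-60)
#' @export
voltage_protocol <- function(kind = c("ramp", "hold"),
                             hold_voltage_mV = -60,
                             ramp_start_mV = -100, ramp_end_mV = 100,
                             duration_s = 0.2,
                             sample_rate_Hz = 10000,
                             filter_cutoff_Hz = 5000) {
  kind <- match.arg(kind)
  stopifnot(duration_s > 0, sample_rate_Hz > 0, filter_cutoff_Hz > 0)
  if (sample_rate_Hz < 2 * filter_cutoff_Hz) {
    stop("sample_rate_Hz must be at least twice filter_cutoff_Hz")
  }
  n <- round(duration_s * sample_rate_Hz)
  stopifnot(n >= 2)
  structure(list(kind = kind,
                 hold_voltage_mV = hold_voltage_mV,
                 ramp_start_mV = ramp_start_mV,
                 ramp_end_mV = ramp_end_mV,
                 duration_s = duration_s,
                 sample_rate_Hz = sample_rate_Hz,
                 filter_cutoff_Hz = filter_cutoff_Hz,
                 n_samples = n),
            class = "voltage_protocol")
}

#' @rdname voltage_protocol
#' @export
ramp_protocol <- function(ramp_start_mV = -100, ramp_end_mV = 100,
                          duration_s = 0.2, sample_rate_Hz = 10000,
                          filter_cutoff_Hz = 5000) {
  voltage_protocol("ramp", ramp_start_mV = ramp_start_mV,
                   ramp_end_mV = ramp_end_mV, duration_s = duration_s,
                   sample_rate_Hz = sample_rate_Hz,
                   filter_cutoff_Hz = filter_cutoff_Hz)
}

#' @rdname voltage_protocol
#' @param hold_voltage_mV Holding potential in mV.
#' @export
hold_protocol <- function(hold_voltage_mV, duration_s = 0.3,
                          sample_rate_Hz = 10000, filter_cutoff_Hz = 5000) {
  voltage_protocol("hold", hold_voltage_mV = hold_voltage_mV,
                   duration_s = duration_s, sample_rate_Hz = sample_rate_Hz,
                   filter_cutoff_Hz = filter_cutoff_Hz)
}

#' Command voltage at each sample of a protocol
#'
#' @param protocol A [voltage_protocol()].
#' @return Numeric vector of membrane potentials (mV), one per sample.
#' @export
protocol_voltage <- function(protocol) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  n <- protocol$n_samples
  if (protocol$kind == "hold") {
    rep(protocol$hold_voltage_mV, n)
  } else {
    seq(protocol$ramp_start_mV, protocol$ramp_end_mV, length.out = n)
  }
}

#' @export
print.voltage_protocol <- function(x, ...) {
  if (x$kind == "hold") {
    cat(sprintf("voltage protocol: hold %g mV, %g s\n",
                x$hold_voltage_mV, x$duration_s))
  } else {
    cat(sprintf("voltage protocol: ramp %g to %g mV in %g s\n",
                x$ramp_start_mV, x$ramp_end_mV, x$duration_s))
  }
  cat(sprintf("  %g Hz sampling, %g Hz low-pass (%d samples)\n",
              x$sample_rate_Hz, x$filter_cutoff_Hz, x$n_samples))
  invisible(x)
}

protocols_equal <- function(a, b) {
  identical(a[c("kind", "hold_voltage_mV", "ramp_start_mV", "ramp_end_mV",
                "duration_s", "sample_rate_Hz", "filter_cutoff_Hz")],
            b[c("kind", "hold_voltage_mV", "ramp_start_mV", "ramp_end_mV",
                "duration_s", "sample_rate_Hz", "filter_cutoff_Hz")])
}
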