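#' Simulate an aperiodic synaptic-current signal
#'
#' Emulates the aperiodic background of field-potential recordings by
#' convolving per-sample Poisson population event counts with a causal
#' exponentially decaying synaptic kernel `exp(-t/tau)` (truncated at
#' `10 * tau`, unnormalized — amplitude scale does not affect the knee). The
#' theoretical power spectrum is Lorentzian with exponent 2 and knee frequency
#' `1/(2*pi*tau_syn)`.
#'
#' @param fs Sampling rate, Hz.
#' @param duration Signal length, seconds.
#' @param tau_syn Synaptic decay constant, seconds. `0` gives a delta kernel
#'   (white shot noise).
#' @param event_rate Aggregate Poisson event rate, events/s. The knee position
#'   does not depend on it; it sets the shot-noise amplitude statistics.
#' @param noise_std Standard deviation of additive white measurement noise.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A [time_series()] of `round(duration * fs)` samples.
#' @export
sim_synaptic_current <- function(fs, duration, tau_syn, event_rate = 1000,
                                 noise_std = 0, seed = 1) {
  if (fs <= 0 || duration <= 0) stop_ts("fs and duration must be positive")
  if (tau_syn < 0) stop_ts("tau_syn must be non-negative")
  if (event_rate <= 0) stop_ts("event_rate must be positive")
  if (tau_syn > 0 && tau_syn * fs < 1)
    stop_ts(sprintf(
      "tau_syn (%g s) is below the sampling resolution 1/fs (%g s)",
      tau_syn, 1 / fs))
  n <- round(duration * fs)
  with_seed_(seed, {
    x <- rpois(n, event_rate / fs)
    if (tau_syn > 0) {
      kt <- seq(0, 10 * tau_syn, by = 1 / fs)
      kern <- exp(-kt / tau_syn)
      # causal convolution with leading zero-padding so no samples are lost
      pad <- length(kern) - 1L
      x <- as.numeric(stats::filter(c(numeric(pad), x), kern,
                                    sides = 1))[pad + seq_len(n)]
    }
    if (noise_std > 0) x <- x + rnorm(n, 0, noise_std)
    time_series(x, fs)
  })
}

#' Add a (possibly frequency-drifting) oscillation to a signal
#'
#' Adds a sinusoid whose instantaneous frequency performs a bounded random
#' walk around `center` (standard deviation `drift_std` Hz accumulated per
#' second, reflected within `center +/- 3 * drift_std`). Frequency drift
#' broadens the resulting spectral peak, the condition under which naive
#' time-domain timescale estimates break down.
#'
#' @param ts A [time_series()].
#' @param center Oscillation center frequency, Hz (< fs/2).
#' @param amplitude Amplitude relative to the signal's standard deviation.
#'   `0` returns the input unchanged.
#' @param drift_std Frequency-drift standard deviation, Hz per sqrt(second).
#' @param seed Integer seed.
#' @return A [time_series()] of the same length and sampling rate.
#' @export
add_oscillation <- function(ts, center, amplitude, drift_std = 0, seed = 1) {
  stopifnot(inherits(ts, "time_series"))
  if (center >= ts$fs / 2) stop_ts("center must be below the Nyquist frequency")
  if (amplitude == 0) return(ts)
  n <- length(ts$samples)
  with_seed_(seed, {
    f_inst <- if (drift_std > 0) {
      walk <- center + cumsum(rnorm(n, 0, drift_std / sqrt(ts$fs)))
      reflect_into(walk, max(center - 3 * drift_std, 0.1),
                   min(center + 3 * drift_std, ts$fs / 2 - 1e-6))
    } else rep(center, n)
    phase <- cumsum(2 * pi * f_inst / ts$fs)
    time_series(ts$samples + amplitude * sd(ts$samples) * sin(phase), ts$fs)
  })
}
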