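#' Uniformly sampled time series
#'
#' Container for a real-valued signal with its sampling rate; the raw material
#' for all spectral estimation in the package.
#'
#' @param samples Numeric vector of signal values (at least 2, all finite).
#' @param fs Sampling rate in Hz (> 0).
#' @return An object of class `time_series` with elements `samples` and `fs`.
#' @export
time_series <- function(samples, fs) {
  if (length(samples) < 2L) stop_ts("a time series needs at least 2 samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_ts("fs must be a single positive number")
  assert_finite(samples, "samples")
  structure(list(samples = as.numeric(samples), fs = fs), class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

duration_s <- function(ts) length(ts$samples) / ts$fs

#' Power spectrum container
#'
#' @param freqs Frequencies in Hz, strictly ascending from 0.
#' @param power Linear power density (units^2/Hz), non-negative.
#' @param fs Sampling rate of the source signal (Hz).
#' @param n_segments Number of windows aggregated into this spectrum.
#' @return An object of class `power_spectrum`.
#' @export
power_spectrum <- function(freqs, power, fs, n_segments = 1L) {
  if (length(freqs) != length(power))
    stop_ts("freqs and power must have equal length")
  if (any(diff(freqs) <= 0) || freqs[1L] < 0)
    stop_ts("freqs must be strictly ascending and start at >= 0")
  if (any(power < 0)) stop_ts("power must be non-negative")
  if (freqs[length(freqs)] > fs / 2 + 1e-9)
    stop_ts("frequencies exceed the Nyquist limit fs/2")
  structure(list(freqs = as.numeric(freqs), power = as.numeric(power),
                 fs = fs, n_segments = as.integer(n_segments)),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, %g-%g Hz (df = %g), %d segment(s)\n",
              length(x$freqs), x$freqs[1L], x$freqs[length(x$freqs)],
              x$freqs[2L] - x$freqs[1L], x$n_segments))
  invisible(x)
}

# one-sided density-scaled squared magnitude of one Hamming-tapered segment;
# scaling 1/(fs*sum(w^2)) makes the white-noise level taper-independent
segment_psd <- function(seg, w, fs, scale, nf, nwin, detrend = "constant") {
  if (detrend == "constant") seg <- seg - mean(seg)
  X <- fft(seg * w)[seq_len(nf)]
  p <- (Mod(X)^2) / scale
  # double all bins except DC and (for even window length) Nyquist
  last_doubled <- if (nwin %% 2L == 0L) nf - 1L else nf
  if (last_doubled >= 2L) p[2L:last_doubled] <- 2 * p[2L:last_doubled]
  p
}

#' Median-Welch power spectral density
#'
#' Short-time tapered Fourier segments are aggregated per frequency with the
#' median across time rather than the mean, suppressing high-amplitude
#' transients. Any final partial window is dropped.
#'
#' @param ts A [time_series()].
#' @param win_s Window length in seconds (frequency resolution = 1/`win_s`).
#' @param overlap Fractional overlap between consecutive windows, in `[0, 1)`.
#' @param aggregate `"median"` (default) or `"mean"`. The median of the
#'   per-segment chi-square power values is biased low by a known constant
#'   factor; it is deliberately not corrected, since all downstream model
#'   fitting is scale-invariant.
#' @param detrend `"constant"` (default) removes each segment's mean before
#'   tapering, so a nonzero signal mean cannot leak into the lowest bins;
#'   `"none"` keeps the raw segment (the DC bin then carries the mean).
#' @return A [power_spectrum()].
#' @export
psd_welch <- function(ts, win_s = 1.0, overlap = 0.5,
                      aggregate = c("median", "mean"),
                      detrend = c("constant", "none")) {
  aggregate <- match.arg(aggregate)
  detrend <- match.arg(detrend)
  stopifnot(inherits(ts, "time_series"))
  if (overlap < 0 || overlap >= 1) stop_ts("overlap must be in [0, 1)")
  fs <- ts$fs
  nwin <- round(win_s * fs)
  if (length(ts$samples) < nwin)
    stop_ts(sprintf("signal too short: need at least %g s (%d samples)",
                    win_s, nwin))
  hop <- max(1L, round((1 - overlap) * nwin))
  starts <- seq.int(1L, length(ts$samples) - nwin + 1L, by = hop)
  w <- as.numeric(signal::hamming(nwin))
  scale <- fs * sum(w^2)
  nf <- nwin %/% 2L + 1L
  segs <- vapply(starts, function(s) {
    segment_psd(ts$samples[s:(s + nwin - 1L)], w, fs, scale, nf, nwin,
                detrend)
  }, numeric(nf))
  pw <- if (aggregate == "median") apply(segs, 1L, median) else rowMeans(segs)
  power_spectrum(freqs = seq(0, by = fs / nwin, length.out = nf), power = pw,
                 fs = fs, n_segments = length(starts))
}

#' Single-epoch power spectrum
#'
#' One Hamming-tapered squared-magnitude Fourier transform of a short epoch
#' (e.g. a 900 ms working-memory period), density-scaled. Frequency
#' resolution is 1/epoch duration.
#'
#' @param epoch A [time_series()] with at least 2 samples.
#' @param detrend As in [psd_welch()].
#' @return A [power_spectrum()] with `n_segments = 1`.
#' @export
psd_epoch <- function(epoch, detrend = c("constant", "none")) {
  detrend <- match.arg(detrend)
  stopifnot(inherits(epoch, "time_series"))
  n <- length(epoch$samples)
  w <- as.numeric(signal::hamming(n))
  scale <- epoch$fs * sum(w^2)
  nf <- n %/% 2L + 1L
  p <- segment_psd(epoch$samples, w, epoch$fs, scale, nf, n, detrend)
  power_spectrum(freqs = seq(0, by = epoch$fs / n, length.out = nf), power = p,
                 fs = epoch$fs, n_segments = 1L)
}

#' Mean log-power in a frequency band
#'
#' Mean of log10 power over bins with `f_lo <= f <= f_hi` (both edges
#' inclusive), as used for narrowband theta (3-8 Hz) and high-gamma
#' (70-100 Hz) summaries.
#'
#' @param psd A [power_spectrum()].
#' @param f_lo,f_hi Band edges in Hz, `f_lo < f_hi`.
#' @return Scalar mean log10 power.
#' @export
band_log_power <- function(psd, f_lo, f_hi) {
  stopifnot(inherits(psd, "power_spectrum"))
  if (f_lo >= f_hi) stop_ts("f_lo must be < f_hi")
  sel <- psd$freqs >= f_lo & psd$freqs <= f_hi
  if (!any(sel)) stop_ts("band does not intersect the spectrum's frequencies")
  mean(log10(psd$power[sel]))
}

#' Moving-average smoothing of a power spectrum
#'
#' Centered `k`-bin moving average of the linear power values. A single
#' tapered periodogram has chi-square(2) sampling noise per bin; mild
#' smoothing trades a little spectral resolution for a large variance
#' reduction, stabilizing aperiodic model fits to short single epochs.
#' Edge bins without a full window are dropped.
#'
#' @param psd A [power_spectrum()].
#' @param k Odd window length in bins; `k = 1` returns the input.
#' @return A [power_spectrum()].
#' @export
smooth_spectrum <- function(psd, k = 3L) {
  stopifnot(inherits(psd, "power_spectrum"), k >= 1L)
  if (k == 1L) return(psd)
  if (k %% 2L == 0L) stop_ts("k must be odd")
  # the DC bin is excluded from all model fits and (after detrending) holds
  # no power; keep it out of its neighbors' averages. Edge bins use
  # truncated windows so no frequencies are lost.
  keep0 <- psd$freqs > 0
  f <- psd$freqs[keep0]
  x <- psd$power[keep0]
  h <- (k - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  p <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  power_spectrum(f, p, psd$fs, psd$n_segments)
}

#' Write / read a power spectrum as delimited text
#'
#' Two columns (`frequency_hz`, `power`) preceded by `#`-prefixed metadata
#' header lines (fs, n_segments).
#'
#' @param psd A [power_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly (writer); a [power_spectrum()] (reader).
#' @export
write_spectrum <- function(psd, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs %.10g", psd$fs),
               sprintf("# n_segments %d", psd$n_segments),
               "frequency_hz\tpower"), con)
  write.table(data.frame(psd$freqs, psd$power), con, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
  get_meta <- function(key) {
    ln <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    as.numeric(sub(paste0("^# ", key, " "), "", ln[1L]))
  }
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  power_spectrum(tab[[1L]], tab[[2L]], fs = get_meta("fs"),
                 n_segments = get_meta("n_segments"))
}
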