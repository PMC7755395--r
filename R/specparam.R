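#' Spectral parameterization of a power spectrum
#'
#' Decomposes a log10 power spectrum into an aperiodic generalized Lorentzian,
#' `L(f) = A / (k + f^chi)` (offset = log10 A, knee `k`, exponent `chi`), plus
#' narrowband Gaussian peaks. The knee parameter maps to the knee frequency
#' `fk = k^(1/chi)` and thence to the neuronal timescale `tau = 1/(2*pi*fk)`.
#'
#' The fit is a deterministic iterative scheme: (1) a robust initial aperiodic
#' fit (fit, drop bins whose positive residual exceeds the 97.5th percentile,
#' refit) so oscillatory peaks do not drag the background; (2) iterative peak
#' detection on the residual — while the largest residual exceeds
#' `peak_threshold_sd` residual standard deviations (and `min_peak_height`),
#' fit and subtract one Gaussian, up to `max_peaks`, merging overlapping peaks
#' (centers closer than 0.75 x summed bandwidths, keeping the taller); (3) a
#' joint refit of all retained peaks; (4) a final aperiodic refit on the
#' peak-subtracted spectrum. All nonlinear fits use bounded Levenberg-Marquardt
#' least squares with fixed starting points, so the result is deterministic.
#'
#' @param psd A [power_spectrum()].
#' @param fit_range Two-element numeric, Hz. Default `c(1, 80)` excludes the
#'   DC bin and the line-noise region; at least 10 bins must fall inside.
#' @param max_peaks Maximum number of Gaussian peaks.
#' @param peak_threshold_sd Peak detection threshold in residual SD units.
#' @param min_peak_height Minimum peak height in log10-power units.
#' @param bandwidth_limits Allowed Gaussian standard deviation range, Hz.
#' @return An object of class `spectral_model`: list with `aperiodic` (named
#'   vector `offset`, `knee`, `exponent`), `peaks` (data.frame `center`,
#'   `height`, `bandwidth`, sorted by center), `fit_range`, `goodness` (named
#'   vector `rmse`, `r2`, on the log10 scale; `NaN` if the fit failed to
#'   converge), `freqs`, `log_power`, and `converged`.
#' @export
fit_spectral_model <- function(psd, fit_range = c(1, 80), max_peaks = 6L,
                               peak_threshold_sd = 2.0, min_peak_height = 0.1,
                               bandwidth_limits = c(0.5, 12)) {
  stopifnot(inherits(psd, "power_spectrum"))
  fit_range <- c(max(fit_range[1L], 0), min(fit_range[2L], psd$fs / 2))
  sel <- psd$freqs >= fit_range[1L] & psd$freqs <= fit_range[2L] &
    psd$freqs > 0
  f <- psd$freqs[sel]
  p <- psd$power[sel]
  if (length(f) < 10L) stop_ts("need at least 10 frequency bins in fit_range")
  if (all(p == 0)) stop_ts("spectrum is all zero within fit_range")
  if (any(p <= 0)) stop_ts("power must be positive within fit_range")
  y <- log10(p)

  ap <- tryCatch(robust_aperiodic_fit(f, y), error = function(e) NULL)
  if (is.null(ap)) return(failed_model(f, y, fit_range))
  flat <- y - aperiodic_log10(ap, f)

  peaks <- detect_peaks(f, flat, max_peaks, peak_threshold_sd,
                        min_peak_height, bandwidth_limits, fit_range)
  peaks <- drop_edge_peaks(merge_overlapping_peaks(peaks), fit_range)
  if (nrow(peaks) > 0L) {
    peaks <- tryCatch(
      refit_peaks_jointly(f, y - aperiodic_log10(ap, f), peaks,
                          bandwidth_limits, fit_range),
      error = function(e) peaks)
    peaks <- drop_edge_peaks(merge_overlapping_peaks(peaks), fit_range)
  }

  ap_final <- tryCatch(
    aperiodic_fit(f, y - peaks_log10(peaks, f), start = ap),
    error = function(e) ap)

  # one more alternation: peaks conditioned on the refit background, then a
  # final background pass — resolves peak/aperiodic trade-off near the knee
  if (nrow(peaks) > 0L) {
    peaks <- tryCatch(
      refit_peaks_jointly(f, y - aperiodic_log10(ap_final, f), peaks,
                          bandwidth_limits, fit_range),
      error = function(e) peaks)
    peaks <- drop_edge_peaks(merge_overlapping_peaks(peaks), fit_range)
    ap_final <- tryCatch(
      aperiodic_fit(f, y - peaks_log10(peaks, f), start = ap_final),
      error = function(e) ap_final)
  }

  model_curve <- aperiodic_log10(ap_final, f) + peaks_log10(peaks, f)
  resid <- y - model_curve
  goodness <- c(rmse = sqrt(mean(resid^2)),
                r2 = 1 - sum(resid^2) / max(sum((y - mean(y))^2), .Machine$double.eps))
  peaks <- peaks[order(peaks$center), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(aperiodic = ap_final, peaks = peaks, fit_range = fit_range,
                 goodness = goodness, freqs = f, log_power = y,
                 converged = TRUE),
            class = "spectral_model")
}

failed_model <- function(f, y, fit_range) {
  structure(list(aperiodic = c(offset = NaN, knee = NaN, exponent = NaN),
                 peaks = empty_peaks(), fit_range = fit_range,
                 goodness = c(rmse = NaN, r2 = NaN), freqs = f, log_power = y,
                 converged = FALSE),
            class = "spectral_model")
}

empty_peaks <- function() {
  data.frame(center = numeric(0), height = numeric(0), bandwidth = numeric(0))
}

# log10 of the generalized Lorentzian with parameters (offset, knee, exponent)
aperiodic_log10 <- function(ap, f) {
  ap[["offset"]] - log10(ap[["knee"]] + f^ap[["exponent"]])
}

peaks_log10 <- function(peaks, f) {
  out <- numeric(length(f))
  if (nrow(peaks) == 0L) return(out)
  for (i in seq_len(nrow(peaks)))
    out <- out + peaks$height[i] *
      exp(-(f - peaks$center[i])^2 / (2 * peaks$bandwidth[i]^2))
  out
}

# bounded LM fit of the aperiodic component; fixed deterministic start
aperiodic_fit <- function(f, y, start = NULL) {
  if (is.null(start)) {
    start <- c(offset = y[1L] + log10(median(f)^2 + f[1L]^2),
               knee = median(f)^2, exponent = 2)
  }
  res <- minpack.lm::nls.lm(
    par = pmin(pmax(unname(start), c(-Inf, 0, 0.1)), c(Inf, Inf, 8)),
    lower = c(-Inf, 0, 0.1), upper = c(Inf, Inf, 8),
    fn = function(par) {
      y - (par[1L] - log10(par[2L] + f^par[3L]))
    },
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (res$info == 0 || any(!is.finite(res$par)))
    stop_ts("aperiodic fit did not converge")
  setNames(res$par, c("offset", "knee", "exponent"))
}

robust_aperiodic_fit <- function(f, y) {
  ap0 <- aperiodic_fit(f, y)
  resid <- y - aperiodic_log10(ap0, f)
  # discard presumed peak regions: bins above the 97.5th residual percentile
  keep <- resid <= quantile(resid, 0.975)
  if (sum(keep) >= 10L) ap0 <- aperiodic_fit(f[keep], y[keep], start = ap0)
  ap0
}

guess_bandwidth <- function(f, flat, imax, bandwidth_limits) {
  h <- flat[imax]
  half <- h / 2
  lo <- imax
  while (lo > 1L && flat[lo - 1L] > half) lo <- lo - 1L
  hi <- imax
  n <- length(flat)
  while (hi < n && flat[hi + 1L] > half) hi <- hi + 1L
  fwhm <- f[hi] - f[lo]
  bw <- if (fwhm > 0) fwhm / 2.355 else diff(bandwidth_limits) / 4
  min(max(bw, bandwidth_limits[1L]), bandwidth_limits[2L])
}

fit_one_gaussian <- function(f, flat, center0, height0, bw0,
                             bandwidth_limits, fit_range) {
  # a maxiter stop still leaves a usable local fit; silence the lmdif notice
  res <- suppressWarnings(minpack.lm::nls.lm(
    par = c(center0, height0, bw0),
    lower = c(fit_range[1L], 0, bandwidth_limits[1L]),
    upper = c(fit_range[2L], Inf, bandwidth_limits[2L]),
    fn = function(par) {
      flat - par[2L] * exp(-(f - par[1L])^2 / (2 * par[3L]^2))
    },
    control = minpack.lm::nls.lm.control(maxiter = 100)))
  setNames(res$par, c("center", "height", "bandwidth"))
}

detect_peaks <- function(f, flat, max_peaks, peak_threshold_sd,
                         min_peak_height, bandwidth_limits, fit_range) {
  peaks <- empty_peaks()
  work <- flat
  while (nrow(peaks) < max_peaks) {
    imax <- which.max(work)
    h <- work[imax]
    if (!is.finite(h) || h < peak_threshold_sd * sd(work) ||
        h < min_peak_height) break
    bw0 <- guess_bandwidth(f, work, imax, bandwidth_limits)
    pk <- tryCatch(
      fit_one_gaussian(f, work, f[imax], h, bw0, bandwidth_limits, fit_range),
      error = function(e) NULL)
    if (is.null(pk) || pk[["height"]] <= 0) break
    work <- work - pk[["height"]] *
      exp(-(f - pk[["center"]])^2 / (2 * pk[["bandwidth"]]^2))
    peaks <- rbind(peaks, as.data.frame(as.list(pk)))
  }
  peaks
}

# peaks whose center sits within one bandwidth of a fit-range edge are
# artifacts of the boundary (typically the Lorentzian plateau or the spectral
# rolloff leaking into the residual) and are discarded, returning their power
# to the aperiodic refit
drop_edge_peaks <- function(peaks, fit_range) {
  if (nrow(peaks) == 0L) return(peaks)
  keep <- (peaks$center - fit_range[1L]) >= peaks$bandwidth &
    (fit_range[2L] - peaks$center) >= peaks$bandwidth
  peaks[keep, , drop = FALSE]
}

# overlapping peaks (centers closer than 0.75 x summed bandwidths) are merged
# by keeping the taller of the pair
merge_overlapping_peaks <- function(peaks) {
  if (nrow(peaks) < 2L) return(peaks)
  peaks <- peaks[order(-peaks$height), , drop = FALSE]
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks) - 1L)) {
    if (!keep[i]) next
    for (j in (i + 1L):nrow(peaks)) {
      if (!keep[j]) next
      if (abs(peaks$center[i] - peaks$center[j]) <
          0.75 * (peaks$bandwidth[i] + peaks$bandwidth[j])) keep[j] <- FALSE
    }
  }
  peaks[keep, , drop = FALSE]
}

refit_peaks_jointly <- function(f, flat, peaks, bandwidth_limits, fit_range) {
  np <- nrow(peaks)
  par0 <- as.numeric(t(as.matrix(peaks)))
  res <- suppressWarnings(minpack.lm::nls.lm(
    par = par0,
    lower = rep(c(fit_range[1L], 0, bandwidth_limits[1L]), np),
    upper = rep(c(fit_range[2L], Inf, bandwidth_limits[2L]), np),
    fn = function(par) {
      m <- matrix(par, ncol = 3L, byrow = TRUE)
      pred <- numeric(length(f))
      for (i in seq_len(np))
        pred <- pred + m[i, 2L] * exp(-(f - m[i, 1L])^2 / (2 * m[i, 3L]^2))
      flat - pred
    },
    control = minpack.lm::nls.lm.control(maxiter = 200)))
  m <- matrix(res$par, ncol = 3L, byrow = TRUE)
  out <- data.frame(center = m[, 1L], height = m[, 2L], bandwidth = m[, 3L])
  out[out$height > 0, , drop = FALSE]
}

#' @export
print.spectral_model <- function(x, ...) {
  cat("<spectral_model>\n")
  if (!x$converged) {
    cat("  fit did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("  aperiodic: offset %.3f, knee %.3f, exponent %.3f\n",
              x$aperiodic[["offset"]], x$aperiodic[["knee"]],
              x$aperiodic[["exponent"]]))
  cat(sprintf("  peaks: %d; fit range %g-%g Hz; rmse %.4f, R^2 %.4f\n",
              nrow(x$peaks), x$fit_range[1L], x$fit_range[2L],
              x$goodness[["rmse"]], x$goodness[["r2"]]))
  fk <- knee_frequency(x)
  if (is.finite(fk))
    cat(sprintf("  knee frequency %.3f Hz, tau %.4f s\n", fk,
                timescale_from_knee(fk)))
  invisible(x)
}

#' Model curve of a fitted spectral model
#'
#' @param object A `spectral_model`.
#' @param freqs Frequencies at which to evaluate (default: the fitted bins).
#' @param component `"full"`, `"aperiodic"`, or `"peaks"`.
#' @param ... Unused.
#' @return Log10-power model values.
#' @export
predict.spectral_model <- function(object, freqs = object$freqs,
                                   component = c("full", "aperiodic", "peaks"),
                                   ...) {
  component <- match.arg(component)
  ap <- aperiodic_log10(object$aperiodic, freqs)
  pk <- peaks_log10(object$peaks, freqs)
  switch(component, full = ap + pk, aperiodic = ap, peaks = pk)
}

#' Knee frequency of an aperiodic fit
#'
#' `fk = k^(1/chi)`; the approximation to the spectral bend is exact when
#' `chi = 2`. A vanishing knee (`k` below `1e-3 * f_min^chi`, with `f_min` the
#' lower fit-range edge) indicates a knee-less pure power-law spectrum, for
#' which the knee frequency — and hence the timescale — is undefined: `NA` is
#' returned rather than an extrapolated value.
#'
#' @param ap A `spectral_model`, or a named vector with `knee` and `exponent`
#'   (optionally `offset`).
#' @param f_min Lower frequency bound used for the knee-less cutoff; taken
#'   from the model's fit range when `ap` is a `spectral_model`.
#' @return Knee frequency in Hz, or `NA_real_` for knee-less spectra.
#' @export
knee_frequency <- function(ap, f_min = 1) {
  if (inherits(ap, "spectral_model")) {
    f_min <- max(ap$fit_range[1L], ap$freqs[1L])
    ap <- ap$aperiodic
  }
  k <- ap[["knee"]]
  chi <- ap[["exponent"]]
  if (!is.finite(k) || !is.finite(chi)) return(NA_real_)
  if (chi <= 0) stop_ts("exponent must be positive")
  if (k < 0) stop_ts("knee must be non-negative")
  if (k < 1e-3 * f_min^chi) return(NA_real_)
  k^(1 / chi)
}

#' Timescale from knee frequency
#'
#' `tau = 1 / (2 * pi * fk)`, the exponential decay constant of the
#' autocorrelation implied by a Lorentzian spectrum with knee `fk`.
#'
#' @param fk Knee frequency in Hz (> 0). `NA` input gives `NA` (knee-less).
#' @return Timescale in seconds.
#' @export
timescale_from_knee <- function(fk) {
  if (length(fk) != 1L) stop_ts("fk must be a scalar")
  if (is.na(fk)) return(NA_real_)
  if (fk <= 0) stop_ts("fk must be positive")
  1 / (2 * pi * fk)
}

#' Timescale estimate from a fitted model
#'
#' @param model A `spectral_model`.
#' @return Named vector `c(fk, tau)`; `NA`s for knee-less or failed fits.
#' @export
timescale_estimate <- function(model) {
  fk <- knee_frequency(model)
  c(fk = fk, tau = if (is.na(fk)) NA_real_ else timescale_from_knee(fk))
}

empirical_acf <- function(ts, max_lag_s) {
  if (max_lag_s >= duration_s(ts) / 2)
    stop_ts("max_lag_s must be below half the signal duration")
  nlag <- floor(max_lag_s * ts$fs)
  a <- acf(ts$samples, lag.max = nlag, plot = FALSE, demean = TRUE)
  list(lag_s = as.numeric(a$lag) / ts$fs, acf = as.numeric(a$acf))
}

#' Naive ACF timescale (time to 1/e)
#'
#' First lag at which the empirical autocorrelation falls to 1/e, linearly
#' interpolated between lags. This naive estimate is biased when oscillations
#' or variable power-law components are present — the motivation for the
#' spectral approach.
#'
#' @param ts A [time_series()].
#' @param max_lag_s Maximum lag in seconds (< duration/2).
#' @return Timescale in seconds.
#' @export
acf_timescale_naive <- function(ts, max_lag_s = 0.5) {
  e <- empirical_acf(ts, max_lag_s)
  thr <- exp(-1)
  below <- which(e$acf <= thr)
  if (length(below) == 0L)
    stop_ts("ACF does not reach 1/e within max_lag_s; timescale unresolved")
  i <- below[1L]
  if (i == 1L) return(0)
  frac <- (e$acf[i - 1L] - thr) / (e$acf[i - 1L] - e$acf[i])
  e$lag_s[i - 1L] + frac * (e$lag_s[i] - e$lag_s[i - 1L])
}

#' ACF timescale by exponential fit
#'
#' Least-squares fit of `exp(-t/tau)` to the empirical autocorrelation over
#' `[0, max_lag_s]`; the time-domain counterpart of the spectral estimate.
#'
#' @param ts A [time_series()].
#' @param max_lag_s Maximum lag in seconds.
#' @return Named vector `c(tau, rmse)`; a large `rmse` flags a poor fit
#'   (e.g. a non-decaying oscillatory ACF).
#' @export
acf_timescale_expfit <- function(ts, max_lag_s = 0.5) {
  e <- empirical_acf(ts, max_lag_s)
  t <- e$lag_s
  a <- e$acf
  tau0 <- max(tryCatch(acf_timescale_naive(ts, max_lag_s),
                       error = function(e) max_lag_s / 5), 1 / ts$fs)
  res <- minpack.lm::nls.lm(
    par = tau0, lower = 1e-6, upper = Inf,
    fn = function(par) a - exp(-t / par),
    control = minpack.lm::nls.lm.control(maxiter = 100))
  c(tau = res$par, rmse = sqrt(mean(res$fvec^2)))
}

#' Serialize / load a fitted spectral model as delimited text
#'
#' One header section per component: aperiodic parameters, peak rows, and
#' goodness of fit.
#'
#' @param model A `spectral_model`.
#' @param path File path.
#' @return `path` invisibly (writer); a reduced `spectral_model` (reader).
#' @export
write_spectral_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("[aperiodic]", con)
  writeLines(sprintf("%s\t%.12g", names(model$aperiodic), model$aperiodic), con)
  writeLines("[peaks]", con)
  writeLines("center\theight\tbandwidth", con)
  if (nrow(model$peaks) > 0L)
    write.table(model$peaks, con, sep = "\t", row.names = FALSE,
                col.names = FALSE)
  writeLines("[goodness]", con)
  writeLines(sprintf("%s\t%.12g", names(model$goodness), model$goodness), con)
  writeLines("[fit_range]", con)
  writeLines(sprintf("%.12g\t%.12g", model$fit_range[1L], model$fit_range[2L]),
             con)
  invisible(path)
}

#' @rdname write_spectral_model
#' @export
read_spectral_model <- function(path) {
  lines <- readLines(path)
  section <- function(name) {
    i <- which(lines == paste0("[", name, "]"))
    j <- grep("^\\[", lines)
    j <- j[j > i]
    end <- if (length(j)) min(j) - 1L else length(lines)
    lines[seq.int(i + 1L, end)]
  }
  kv <- function(x) {
    parts <- strsplit(x, "\t")
    setNames(vapply(parts, function(p) as.numeric(p[2L]), 0),
             vapply(parts, `[`, "", 1L))
  }
  pk_lines <- section("peaks")[-1L]
  peaks <- if (length(pk_lines) == 0L) empty_peaks() else {
    m <- do.call(rbind, lapply(strsplit(pk_lines, "\t"), as.numeric))
    data.frame(center = m[, 1L], height = m[, 2L], bandwidth = m[, 3L])
  }
  fr <- as.numeric(strsplit(section("fit_range")[1L], "\t")[[1L]])
  structure(list(aperiodic = kv(section("aperiodic")), peaks = peaks,
                 fit_range = fr, goodness = kv(section("goodness")),
                 freqs = numeric(0), log_power = numeric(0), converged = TRUE),
            class = "spectral_model")
}
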