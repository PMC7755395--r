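#' Per-trial working-memory spectral features
#'
#' Fits the spectral model to the single-epoch PSDs of one trial's baseline
#' and two delay epochs and derives: baseline timescale, delay timescale
#' (the two delay estimates combined on the log scale, i.e. their geometric
#' mean — single-trial timescale estimates are approximately log-normal, the
#' same reason the baseline-to-delay change is taken as a log difference),
#' their natural-log difference
#' (`delta_log_tau = log(tau_delay) - log(tau_baseline)`), and
#' delay-minus-baseline deltas of theta (3-8 Hz) log-power, high-gamma
#' (70-100 Hz) log-power, and the aperiodic exponent.
#'
#' @param baseline,delay1,delay2 [time_series()] epochs of one trial.
#' @param fit_range,max_peaks Passed to [fit_spectral_model()].
#' @param smooth_bins Moving-average window (bins) applied to each epoch
#'   periodogram before fitting (see [smooth_spectrum()]); single 900 ms
#'   periodograms carry chi-square(2) noise per bin, and mild smoothing keeps
#'   the per-epoch knee estimates stable. `1` disables smoothing.
#' @return One-row data.frame of features, or `NULL` when any epoch's fit
#'   fails or yields an undefined timescale (the trial is dropped).
#' @export
wm_trial_features <- function(baseline, delay1, delay2,
                              fit_range = c(1, 80), max_peaks = 2L,
                              smooth_bins = 3L) {
  fit_one <- function(ep) {
    psd <- psd_epoch(ep)
    m <- tryCatch(fit_spectral_model(smooth_spectrum(psd, smooth_bins),
                                     fit_range = fit_range,
                                     max_peaks = max_peaks),
                  error = function(e) NULL)
    if (is.null(m) || !m$converged || !is.finite(m$goodness[["rmse"]]))
      return(NULL)
    fk <- knee_frequency(m)
    # a knee outside the fitted band is not resolved by the fit; treat the
    # epoch as a failed estimate rather than extrapolating
    if (!is.finite(fk) || fk < fit_range[1L] || fk > fit_range[2L])
      return(NULL)
    tau <- timescale_from_knee(fk)
    list(tau = tau, exponent = unname(m$aperiodic[["exponent"]]),
         theta = band_log_power(psd, 3, 8),
         hgamma = band_log_power(psd, 70, 100))
  }
  fb <- fit_one(baseline)
  f1 <- fit_one(delay1)
  f2 <- fit_one(delay2)
  if (is.null(fb) || is.null(f1) || is.null(f2)) return(NULL)
  tau_delay <- exp(mean(log(c(f1$tau, f2$tau))))
  data.frame(
    baseline_tau = fb$tau, delay_tau = tau_delay,
    delta_log_tau = log(tau_delay) - log(fb$tau),
    delta_theta = mean(c(f1$theta, f2$theta)) - fb$theta,
    delta_hgamma = mean(c(f1$hgamma, f2$hgamma)) - fb$hgamma,
    delta_exponent = mean(c(f1$exponent, f2$exponent)) - fb$exponent)
}

#' Subject-by-region working-memory features from epoched trials
#'
#' Applies [wm_trial_features()] to every trial, then aggregates in the
#' fixed order channels -> trials -> subject: within each trial features are
#' averaged across channels of a region, then across trials. Trials with any
#' failed epoch fit are dropped and counted.
#'
#' @param trial_data A dataset shaped like [generate_trial_dataset()]'s
#'   output (`epochs` list with subject/region/channel/period/trial/ts).
#' @param ... Passed to [wm_trial_features()].
#' @return data.frame with one row per subject x region: `subject_id`,
#'   `region`, the averaged features, `n_trials`, `n_dropped`.
#' @export
wm_cohort_features <- function(trial_data, ...) {
  ep <- trial_data$epochs
  key <- vapply(ep, function(e)
    paste(e$subject_id, e$region, e$channel_id, e$trial, sep = "\r"), "")
  period <- vapply(ep, `[[`, "", "period")
  groups <- split(seq_along(ep), key)
  trial_rows <- lapply(groups, function(idx) {
    per <- period[idx]
    need <- c("baseline", "delay1", "delay2")
    if (!all(need %in% per)) return(NULL)
    ft <- wm_trial_features(ep[[idx[match("baseline", per)]]]$ts,
                            ep[[idx[match("delay1", per)]]]$ts,
                            ep[[idx[match("delay2", per)]]]$ts, ...)
    if (is.null(ft)) return(ft)
    e0 <- ep[[idx[1L]]]
    cbind(data.frame(subject_id = e0$subject_id, region = e0$region,
                     channel_id = e0$channel_id, trial = e0$trial,
                     stringsAsFactors = FALSE), ft)
  })
  dropped <- sum(vapply(trial_rows, is.null, TRUE))
  tab <- do.call(rbind, trial_rows[!vapply(trial_rows, is.null, TRUE)])
  if (is.null(tab) || nrow(tab) == 0L)
    stop_ts("no trial produced a complete set of spectral fits")
  feat_cols <- c("baseline_tau", "delay_tau", "delta_log_tau", "delta_theta",
                 "delta_hgamma", "delta_exponent")
  # channels -> trials: average channels within subject x region x trial
  by_trial <- aggregate(tab[feat_cols],
                        tab[c("subject_id", "region", "trial")], mean)
  # trials -> subject
  out <- aggregate(by_trial[feat_cols],
                   by_trial[c("subject_id", "region")], mean)
  counts <- aggregate(list(n_trials = by_trial$trial),
                      by_trial[c("subject_id", "region")], length)
  out <- merge(out, counts, by = c("subject_id", "region"))
  out <- out[order(out$subject_id, out$region), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_trials") <- dropped
  out
}

#' Region-level working-memory statistics
#'
#' Two families of two-sided tests on the subject-level features:
#' pairwise Mann-Whitney U tests of baseline timescale between regions (the
#' hierarchy check), and per-region Wilcoxon signed-rank tests of
#' `delta_log_tau` against zero (the delay-expansion check). Regions with a
#' single subject are excluded from the pairwise tests.
#'
#' @param features Output of [wm_cohort_features()].
#' @return List with `baseline_pairwise` (data.frame `region_a`, `region_b`,
#'   `statistic`, `p`) and `delay_change` (data.frame `region`, `n`,
#'   `median_delta_log_tau`, `median_expansion`, `statistic`, `p`).
#' @export
wm_region_stats <- function(features) {
  regs <- unique(features$region)
  by_reg <- split(features, features$region)
  usable <- names(by_reg)[vapply(by_reg, nrow, 0L) >= 2L]
  pair_rows <- list()
  if (length(usable) >= 2L) {
    cmb <- utils::combn(usable, 2L)
    pair_rows <- lapply(seq_len(ncol(cmb)), function(i) {
      a <- by_reg[[cmb[1L, i]]]$baseline_tau
      b <- by_reg[[cmb[2L, i]]]$baseline_tau
      w <- wilcox.test(a, b, exact = FALSE)
      data.frame(region_a = cmb[1L, i], region_b = cmb[2L, i],
                 statistic = unname(w$statistic), p = w$p.value,
                 stringsAsFactors = FALSE)
    })
  }
  delay_rows <- lapply(names(by_reg), function(rg) {
    d <- by_reg[[rg]]$delta_log_tau
    w <- wilcox.test(d, mu = 0, exact = FALSE)   # one-sample signed-rank
    data.frame(region = rg, n = length(d),
               median_delta_log_tau = median(d),
               median_expansion = exp(median(d)),
               statistic = unname(w$statistic), p = w$p.value,
               stringsAsFactors = FALSE)
  })
  list(baseline_pairwise = if (length(pair_rows))
         do.call(rbind, pair_rows) else NULL,
       delay_change = do.call(rbind, delay_rows))
}

#' Timescale-expansion vs. behavior correlation
#'
#' Spearman correlation between subjects' mean delay-period log-timescale
#' change and their working-memory accuracy, computed for every region (the
#' headline region being PFC).
#'
#' @param features Output of [wm_cohort_features()].
#' @param accuracy data.frame `subject_id`, `accuracy`.
#' @param min_subjects Minimum subjects with both measures per region.
#' @return data.frame `region`, `n`, `rho`, `p`.
#' @export
wm_behavior_correlation <- function(features, accuracy, min_subjects = 5L) {
  j <- merge(features, accuracy, by = "subject_id")
  do.call(rbind, lapply(split(j, j$region), function(d) {
    if (nrow(d) < min_subjects) return(NULL)
    ct <- cor.test(d$delta_log_tau, d$accuracy, method = "spearman",
                   exact = FALSE)
    data.frame(region = d$region[1L], n = nrow(d),
               rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
}

#' Normalized per-subject average cortical timescale
#'
#' Because electrode coverage is sparse and idiosyncratic, raw within-subject
#' parcel averages confound aging with the spatial hierarchy. Each parcel
#' column is therefore first normalized by its maximum across subjects
#' (missing entries ignored, never imputed); subjects are then averaged over
#' their own valid parcels, and subjects with fewer than `min_valid_parcels`
#' valid parcels are excluded.
#'
#' @param tau_matrix Subjects x parcels matrix, `NA` = missing.
#' @param min_valid_parcels Minimum valid parcels per retained subject.
#' @return List with `means` (named per-subject normalized means),
#'   `n_valid` (per-subject valid-parcel counts), `excluded_subjects`,
#'   `dropped_parcels` (parcels with non-positive maxima).
#' @export
aging_subject_means <- function(tau_matrix, min_valid_parcels = 10L) {
  M <- as.matrix(tau_matrix)
  cmax <- suppressWarnings(apply(M, 2L, max, na.rm = TRUE))
  bad <- !is.finite(cmax) | cmax <= 0
  if (any(bad))
    message(sprintf("dropping %d parcel(s) with non-positive maxima", sum(bad)))
  Mn <- sweep(M[, !bad, drop = FALSE], 2L, cmax[!bad], "/")
  n_valid <- rowSums(!is.na(Mn))
  keep <- n_valid >= min_valid_parcels
  if (!any(keep)) stop_ts("no subject reaches min_valid_parcels")
  means <- rowMeans(Mn[keep, , drop = FALSE], na.rm = TRUE)
  list(means = means, n_valid = n_valid,
       excluded_subjects = rownames(M)[!keep],
       dropped_parcels = colnames(M)[bad])
}

#' Age vs. average-timescale correlation
#'
#' @param means Named per-subject normalized means
#'   (see [aging_subject_means()]); names must index into `ages`' order or
#'   `ages` must already be restricted to the same subjects.
#' @param ages Ages in years for the same subjects, in the same order.
#' @return List `rho`, `p`, `n`.
#' @export
aging_age_correlation <- function(means, ages) {
  if (length(means) != length(ages))
    stop_ts("means and ages must be aligned to the same subjects")
  if (length(means) < 10L) stop_ts("need at least 10 subjects")
  ct <- cor.test(ages, means, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(means))
}

#' Parcel-wise age-timescale association
#'
#' Spearman correlation between age and timescale within each parcel over
#' the subjects with data there (parcels with fewer than `min_subjects`
#' masked), summarized by a two-sided one-sample t-test of the per-parcel
#' correlations against zero.
#'
#' @param tau_matrix Subjects x parcels matrix, `NA` = missing.
#' @param ages Ages in years, one per subject row.
#' @param min_subjects Minimum subjects per tested parcel.
#' @return List with `parcel_rho` (named, `NA` where masked), `n_parcels`,
#'   `t`, `p`, `mean_rho`.
#' @export
aging_parcelwise <- function(tau_matrix, ages, min_subjects = 5L) {
  M <- as.matrix(tau_matrix)
  stopifnot(nrow(M) == length(ages))
  rho <- vapply(seq_len(ncol(M)), function(j) {
    ok <- !is.na(M[, j])
    if (sum(ok) < min_subjects) return(NA_real_)
    cor(ages[ok], M[ok, j], method = "spearman")
  }, 0)
  names(rho) <- colnames(M)
  tested <- rho[!is.na(rho)]
  if (length(tested) < 2L)
    return(list(parcel_rho = rho, n_parcels = length(tested),
                t = NA_real_, p = NA_real_,
                mean_rho = if (length(tested)) mean(tested) else NA_real_))
  tt <- t.test(tested, mu = 0)
  list(parcel_rho = rho, n_parcels = length(tested),
       t = unname(tt$statistic), p = tt$p.value, mean_rho = mean(tested))
}
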