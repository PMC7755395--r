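---
title: "Inferring neuronal timescales from field-potential spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring neuronal timescales from field-potential spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauspec)
```

## The model

Aperiodic (non-rhythmic) field-potential activity behaves, to first
approximation, like shot noise: Poisson population events convolved with an
exponentially decaying synaptic kernel `exp(-t/tau)`. The autocorrelation of
such a process decays as `exp(-t/tau)`, and its power spectrum is a
generalized Lorentzian,

    L(f) = A / (k + f^chi),

flat below a bend — the knee frequency — and power-law above it. `tauspec`
estimates `tau` in the frequency domain: the log10 spectrum is decomposed
into this aperiodic component plus Gaussian peaks for narrowband
oscillations, the knee frequency is `fk = k^(1/chi)` (exact when `chi = 2`),
and

    tau = 1 / (2 * pi * fk).

Fitting in the frequency domain matters because oscillations corrupt the
naive time-domain estimate (the lag where the ACF reaches 1/e) far more than
they corrupt the spectral fit, where they are absorbed by the Gaussian peak
terms and discarded. A drifting oscillation frequency — a broad spectral
peak — needs a single Gaussian in the frequency domain but many cosine terms
in the ACF.

```{r}
ts <- sim_synaptic_current(fs = 1000, duration = 60, tau_syn = 0.02, seed = 1)
model <- fit_spectral_model(psd_welch(ts))
timescale_estimate(model)   # truth: tau = 0.020 s, fk ~ 7.96 Hz
```

## Spectral estimation choices

* **Median Welch.** `psd_welch()` aggregates 1 s Hamming-tapered segments
  (50% overlap) with the per-frequency *median*, so a single high-amplitude
  transient cannot inflate the spectrum. The median of exponentially
  distributed per-segment power is biased low by a constant factor (ln 2);
  we do not correct it because every downstream quantity (knee, exponent,
  peaks, tau) is invariant to rescaling the spectrum. The `aggregate =
  "mean"` switch exists for checks that need an unbiased level, e.g. the
  Parseval identity.
* **Detrending.** Each segment's mean is removed before tapering (the
  `detrend = "constant"` default). Without this, a nonzero signal mean leaks
  through the taper's mainlobe into the lowest one or two bins — exactly the
  bins that determine the knee. `detrend = "none"` is available for
  DC-sensitive uses.
* **Single epochs.** `psd_epoch()` is one Hamming-tapered periodogram, used
  for 900 ms task epochs where stationarity across a longer window cannot be
  assumed.
* **Bands.** Band summaries (`band_log_power()`) average log10 power over
  closed intervals — 3–8 Hz theta and 70–100 Hz high-gamma include both
  edges.

## Fitting: parameters that matter

`fit_spectral_model()` is deterministic: bounded Levenberg–Marquardt with a
fixed starting point (offset from the first bin's log power, `k` =
median-frequency squared, `chi = 2`).

* `fit_range = c(1, 80)` Hz. The DC bin is always excluded; 80 Hz keeps
  clear of mains interference in typical recordings. The range is a package
  default, configurable per call.
* `chi` is bounded to `[0.1, 8]` (neural spectra typically show 2–6);
  peak bandwidths to `[0.5, 12]` Hz.
* The robust initial aperiodic fit drops bins whose positive residual
  exceeds the 97.5th percentile (presumed peak regions) and refits.
* Peaks are detected largest-residual-first while the residual maximum
  exceeds `peak_threshold_sd` residual standard deviations, then overlapping
  peaks (centers closer than 0.75 x summed bandwidths) are merged keeping
  the taller, and peaks whose center lies within one bandwidth of a
  fit-range edge are discarded — edge "peaks" are almost always the
  Lorentzian plateau or rolloff leaking into the residual, and returning
  that power to the final aperiodic refit is essential for unbiased knees.
* A fitted knee below `1e-3 * f_min^chi` means the bend lies far below the
  fitted band: the spectrum is effectively a pure power law and `fk`, `tau`
  are reported as undefined (`NA`) rather than extrapolated.

## Projection and group maps

Sparse electrodes are extrapolated with the Gaussian confidence mask
`w(r) = exp(-r^2/alpha^2)`, with `alpha = 4/sqrt(ln 2)` (~4.80 mm) chosen so
that a location 4 mm from an electrode has 50% confidence; a location under
an electrode has confidence 1. Every electrode contributes to every point
(no hard cutoff), point values are weight-normalized averages, parcel values
confidence-weighted means over member points, and group maps
confidence-weighted means over subjects. Parcels with confidence below 0.5
(no electrode within 4 mm) are invalid by default. Values are averaged on
the linear scale, matching how per-electrode timescales are combined in
practice.

## Spatial inference

Cortical maps are spatially autocorrelated, so correlating two maps against
a shuffled null wildly overstates significance. `msr_nulls()` implements
Moran spectral randomization: the map is expressed in the eigenvector basis
of the doubly centered inverse-distance weight matrix and each surrogate
randomizes the signs of the spectral coefficients (the singleton
procedure). Sign flips preserve the map's mean, variance, and Moran's I
*exactly*, and the nulls are uncorrelated with the source map in
expectation; the constant direction (zero-eigenvalue eigenvector aligned
with the all-ones vector) is excluded from randomization. P-values use the
add-one rule, `p = (1 + #{|rho_null| >= |rho|})/(n_null + 1)`, so they are
bounded below by `1/(n_null + 1)` and never zero. Equal-pair-count
variogram bins keep long-distance bins from being variance-starved.

## Transcriptomic association

Expression is normalized per gene (mean 0, variance 1 across parcels)
before PCA and PLS; raw values are kept for the brain-specificity rule
(brain mean strictly greater than four times the all-tissue median). PCA
signs are fixed by making each component positively correlated with its
highest-loading gene. "PLS weight" here is the first-component x-weight
vector, proportional to the per-gene covariance with the response — with a
single response and one component this is the covariance direction, and it
is what the null-map selection thresholds: a gene is selected when its
absolute empirical weight exceeds the 95th percentile of its own null
distribution obtained by refitting against spatial-autocorrelation-
preserving nulls of the response map. Enrichment uses two-sided Fisher's
exact tests per term (both enriched and purified directions are of
interest), Benjamini–Hochberg adjustment, and the ratio `(b/n)/(B/N)`;
terms are tested independently with no ontology-graph propagation.

## Cohort analyses

**Working memory.** Per trial, the baseline epoch and the two delay epochs
are fit separately on their single-epoch spectra; the two delay timescales
are combined on the log scale (geometric mean), and the trial's effect is
`delta_log_tau = log(tau_delay) - log(tau_baseline)`. Natural logs are used
because single-trial timescale estimates are approximately log-normal —
the same reason the delay pair is combined geometrically: combining
right-skewed estimates arithmetically before taking logs adds a systematic
Jensen-gap inflation of about a quarter of the log-variance that the
baseline term (a single estimate) does not share. Single-epoch periodograms
are smoothed with a 3-bin moving average (`smooth_spectrum()`) before
fitting; a fitted knee outside the fitted band is treated as a failed
epoch, and a trial with any failed epoch is dropped and counted rather than
imputed. Aggregation order is fixed: channels within region, then trials,
then subjects. Hierarchy uses pairwise two-sided Mann–Whitney U tests on
baseline timescales; delay change uses per-region two-sided Wilcoxon
signed-rank tests (the paired-by-design comparison), and behavior the
Spearman correlation between subject mean `delta_log_tau` and accuracy,
reported for every region with prefrontal cortex as the headline.

**Aging.** Coverage is sparse and idiosyncratic, so raw within-subject
parcel means confound age with the spatial gradient. Each parcel is first
normalized by its maximum across subjects, subjects below 10 valid parcels
are excluded, and the per-subject mean is correlated with age; parcel-wise
correlations (at least 5 subjects per parcel) are summarized by a one-sample
t-test. Missing parcels are never imputed.

## What the synthetic generators emulate — and what they do not

The generators produce every input with known ground truth: shot-noise
signals with planted `tau` (default event rate 1000 events/s — the knee
does not depend on the rate, which only sets amplitude statistics);
drifting oscillations (bounded random walk of instantaneous frequency, std
`drift_std` per second, reflected at three standard deviations); a
180-parcel Fibonacci sphere of ~100 mm diameter with great-circle parcel
distances standing in for a parcellated hemisphere with geodesic distances;
Gaussian random fields with squared-exponential covariance
(`exp(-d^2/(2*l^2))`, default `l` = 20 mm) as smooth cortical maps; sparse
electrode cohorts; expression matrices with a planted gene subset tracking
a target map; epoched trial cohorts with a planted delay expansion; and
aging cohorts with a planted linear compression (0.005/yr over ages 13–62,
71 subjects).

They deliberately do **not** emulate line noise, artifacts, epileptiform
activity, volume conduction, real cortical folding, or the probe-level
structure of microarray data. Passing the recovery suites therefore shows
the *estimators* are correct and calibrated under the stated statistical
structure, not that any particular real dataset would yield particular
values.

### Study conditions used by the validation suites

Chosen once, as the package's own study design:

* Timescale recovery: 24 signals, `tau` log-spaced 5–100 ms, 60 s at
  1000 Hz.
* Spatial calibration: 200 independent map pairs on 180 parcels
  (`l` = 20 mm), 500 nulls each.
* Gene selection: 1000 genes, 50 planted at effect 1 with SA noise 0.5,
  500 nulls.
* Working memory: 14 subjects, 900 ms epochs at 1000 Hz, baseline
  timescales PC 20 / PFC 25 / OFC 30 / MTL 35 ms (the hierarchical ordering
  of association regions at the human ECoG scale), 40 trials per region,
  delay expansion 1.2. The expansion-recovery check uses a homogeneous
  cohort (every subject exactly 1.2, so the planted cohort value is
  well-defined); the behavior check uses a dispersed cohort (subject
  log-expansions spread with sd 0.1 — between-subject variance is the very
  thing a behavior correlation needs) with accuracy a logistic function of
  the subject's prefrontal log-expansion plus small noise.
* Aging: 71 subjects, ages 13–62, 5–30 electrodes per subject,
  compression 0.005/yr, electrode noise 10% of map sd.

## Numerical and degenerate-input policy

Nonlinear fits never throw on difficult spectra: a non-converged model is
returned flagged with `NaN` goodness. All-zero spectra, empty bands, empty
study sets, constant covariates, and zero-variance maps raise immediate
errors naming the problem. Covariance factorizations add escalating
diagonal jitter when needed and say so. Per-stage seeds are derived from
one global seed by a fixed affine counter, so any stage can be rerun in
isolation; every generator is bit-reproducible given its seed.

## Known limitations

Single-epoch (900 ms) knee estimates are intrinsically noisy and
right-skewed; the cohort pipeline manages this with log-domain statistics,
mild smoothing, and in-band checks, but per-trial values should never be
interpreted individually. The spectral model fits one knee only — spectra
with multiple bends or low-frequency plateaus are out of scope. MSR
operates at parcel resolution; vertex-level surrogates and alternative null
engines (variogram fitting, spin permutation) are not implemented, though
the ensemble carries a method tag so they can be added. The fit range,
bounds, and thresholds are package defaults; there is no canonical
published setting for any given dataset, and sensitivity to these choices
should be checked per application.
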