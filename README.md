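# tauspec

Neuronal timescales — the exponential decay constants of neural
autocorrelation — lengthen along the cortical hierarchy, from sensory to
association regions, and index how long a circuit can hold information.
`tauspec` infers these timescales from field-potential recordings in the
frequency domain and implements the spatial, transcriptomic, and behavioral
analyses that such timescale maps feed into. It is aimed at
electrophysiologists and systems neuroscientists working with intracranial
(ECoG/iEEG) or simulated population signals.

## The method

The power spectrum of aperiodic neural activity follows a generalized
Lorentzian

```
L(f) = A / (k + f^chi)
```

flat below the *knee frequency* `fk = k^(1/chi)` and power-law above it.
Because the spectrum is the Fourier transform of the autocorrelation, the
knee determines the timescale exactly:

```
tau = 1 / (2 * pi * fk)
```

`tauspec` fits the log10 spectrum as this aperiodic component plus Gaussian
peaks for narrowband oscillations (which would otherwise corrupt the naive
time-domain estimate of `tau`), discards the peaks, and converts the knee to
a timescale. Around this core the package provides:

* median-Welch and single-epoch spectral estimation (`psd_welch()`,
  `psd_epoch()`, `band_log_power()`);
* spectral parameterization and ACF-based cross-checks
  (`fit_spectral_model()`, `knee_frequency()`, `timescale_from_knee()`,
  `acf_timescale_naive()`, `acf_timescale_expfit()`);
* Gaussian confidence-mask projection of sparse electrodes onto a
  parcellation, `w(r) = exp(-r^2/alpha^2)` with `w(4 mm) = 0.5`
  (`project_subject()`, `aggregate_to_parcels()`, `combine_subjects()`);
* spatial-autocorrelation-preserving null maps via Moran spectral
  randomization and SA-corrected Spearman inference (`msr_nulls()`,
  `sa_corrected_correlation()`, `moran_I()`, `variogram()`);
* transcriptomic association: brain-specific gene selection, expression
  PCA, one-component PLS with null-map gene significance, and GO enrichment
  by Fisher's exact test with BH correction (`expression_pca()`,
  `pls1_weights()`, `null_pls_gene_selection()`, `go_enrichment()`,
  `cross_scale_comparison()`);
* working-memory (baseline vs. delay timescale expansion, behavior
  correlation) and aging (cortex-wide timescale compression) cohort
  analyses (`wm_cohort_features()`, `wm_region_stats()`,
  `aging_subject_means()`, `aging_parcelwise()`);
* synthetic-data generators with known ground truth for every input
  (`sim_synaptic_current()`, `generate_sa_map()`,
  `generate_electrode_dataset()`, `generate_expression_matrix()`,
  `generate_trial_dataset()`, `generate_aging_cohort()`,
  `generate_toy_ontology()`), and an end-to-end benchmark
  (`run_pipeline()`).

See `vignettes/timescale-methods.Rmd` for the model, parameter choices, and
validation design.

## Worked example

Simulate 60 s of aperiodic activity with a 50 ms synaptic timescale plus a
strong, drifting 10 Hz oscillation, and recover the timescale from the
spectrum:

```r
library(tauspec)

ts  <- sim_synaptic_current(fs = 1000, duration = 60, tau_syn = 0.05, seed = 7)
osc <- add_oscillation(ts, center = 10, amplitude = 1, drift_std = 1, seed = 8)
model <- fit_spectral_model(psd_welch(osc))
model
#> <spectral_model>
#>   aperiodic: offset 1.568, knee 10.889, exponent 2.002
#>   peaks: 1; fit range 1-80 Hz; rmse 0.0646, R^2 0.9929
#>   knee frequency 3.297 Hz, tau 0.0483 s
timescale_estimate(model)
#>         fk        tau 
#> 3.29681405 0.04827538
acf_timescale_naive(osc, max_lag_s = 0.5)
#> [1] 0.02421266
```

The fitted knee (3.30 Hz) sits near the theoretical 3.18 Hz for a 50 ms
kernel, so the spectral estimate (48.3 ms) lands within 4% of the ground
truth: the oscillation is absorbed by one Gaussian peak and discarded. The
naive ACF-to-1/e estimate on the same signal (24.2 ms) is pulled more than
50% off by the oscillation. On the oscillation-free signal the time-domain
exponential fit agrees with the spectral estimate
(`acf_timescale_expfit(ts, 0.3)` gives 46.7 ms), which is the
Wiener–Khinchin consistency the test suite enforces.

The projection calibration in numbers:

```r
default_alpha()                      # 4.804530, mm
gaussian_weight(0)                   # 1.0  : confidence under an electrode
gaussian_weight(4)                   # 0.5  : confidence 4 mm away
```

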