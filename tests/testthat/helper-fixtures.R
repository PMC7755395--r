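# shared fixtures, built once per test run

# small spherical geometry: 60 parcels x 4 points keeps spatial tests fast
test_geom <- sphere_geometry(n_parcels = 60L, points_per_parcel = 4L,
                             seed = 11)
test_W <- inverse_distance_weights(test_geom$parcel_distance)

# full-size geometry for tests that exercise the 180-parcel study layout
full_geom_cache <- new.env(parent = emptyenv())
full_geom <- function() {
  if (is.null(full_geom_cache$g))
    full_geom_cache$g <- sphere_geometry(n_parcels = 180L,
                                         points_per_parcel = 8L, seed = 11)
  full_geom_cache$g
}

# noiseless spectrum from an exact generalized Lorentzian, optionally with
# Gaussian peaks added in the log10 domain
lorentzian_psd <- function(freqs = seq(0.5, 100, by = 0.5), A = 1, k = 100,
                           chi = 2, peaks = NULL, fs = 1000) {
  logp <- log10(A) - log10(k + freqs^chi)
  if (!is.null(peaks))
    for (i in seq_len(nrow(peaks)))
      logp <- logp + peaks$height[i] *
        exp(-(freqs - peaks$center[i])^2 / (2 * peaks$bandwidth[i]^2))
  power_spectrum(freqs, 10^logp, fs = fs)
}

# independent two-sided Fisher p oracle: full hypergeometric enumeration
fisher_p_oracle <- function(b, B, n, N) {
  bs <- max(0L, n + B - N):min(n, B)
  d <- dhyper(bs, B, N - B, n)
  sum(d[d <= d[match(b, bs)] * (1 + 1e-7)])
}
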