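Package: tauspec
Title: Neuronal Timescales from Field-Potential Power Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers neuronal timescales from intracranial field-potential
    recordings by parameterizing power spectra into an aperiodic generalized
    Lorentzian (offset, knee, exponent) plus Gaussian oscillatory peaks, and
    converting the knee frequency into an autocorrelation decay constant
    (tau = 1/(2*pi*fk)). Includes median-Welch and single-epoch spectral
    estimation, Gaussian confidence-mask projection of sparse electrode values
    onto a cortical parcellation, spatial-autocorrelation-preserving null maps
    via Moran spectral randomization with SA-corrected Spearman inference,
    a transcriptomic association suite (expression PCA, one-component PLS with
    null-map gene selection, gene-ontology enrichment by Fisher's exact test),
    working-memory and aging cohort analyses, and synthetic-data generators
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    signal,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
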