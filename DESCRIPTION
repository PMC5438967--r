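Package: amideR
Title: Amide I Band Deconvolution for Protein Secondary-Structure Quantification from Raman Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to quantify protein secondary-structure motif abundances
    (alpha-helix, beta-sheet, beta-turn, unordered, amino-acid side-chain and
    aromatic-ring modes) from the amide I band (1590-1710 1/cm) of tissue Raman
    spectra. Implements a full preprocessing chain (cosmic-ray despiking,
    baseline correction, vector normalization, spectral averaging,
    Savitzky-Golay smoothing, band cropping), second-derivative sub-band
    detection, bounded multi-Gaussian least-squares deconvolution, wavenumber
    window assignment of fitted band centers to structural motifs, relative
    area-based abundance computation, and exposure time-course trend summaries.
    Includes a synthetic-spectrum generator (Gaussian sub-band mixtures with
    fluorescence baseline, noise and cosmic-ray spikes) used as the test bed
    for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    minpack.lm,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
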