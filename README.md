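# amideR

Quantification of protein secondary-structure motif abundances from the
amide I band of Raman spectra.

## The problem

The amide I band (~1600–1700 cm⁻¹) of a protein or tissue Raman spectrum is
dominated by peptide-bond C=O stretching, and its shape encodes the mix of
secondary-structure motifs present: α-helix, β-sheet, β-turn and unordered
(random-coil) backbone, overlapped by amino-acid side-chain and aromatic
ring modes at the low-wavenumber edge. Because the individual sub-bands
overlap heavily, the envelope must be deconvolved — decomposed into Gaussian
components — before the motif composition can be read off. This is the
standard way to follow conformational transitions such as the α-helix →
β-sheet conversion of amyloid-β 1–42 during neurodegeneration.

`amideR` implements the whole workflow for point Raman spectra of tissue:

1. **Preprocessing** — cosmic-ray despiking (running-median/modified-z
   replacement), baseline correction (iteratively clipped polynomial or
   asymmetric least squares), vector normalization, averaging of the
   per-section spectra, Savitzky–Golay smoothing (5-point window), crop to
   1590–1710 cm⁻¹.
2. **Band counting** — sub-band positions located as the negative-lobe
   minima of the Savitzky–Golay second derivative of the amide I envelope,
   with close candidates merged; an explicit band inventory can be supplied
   instead when it is known.
3. **Deconvolution** — bounded Levenberg–Marquardt least squares of a sum of
   Gaussians `a·exp(−4 ln2 ((ν−c)/w)²)`, one per candidate: centers within
   ±6 cm⁻¹ of their seeds, widths within 8–45 cm⁻¹, amplitudes ≥ 0.
   Band areas are computed analytically as `a·w·√(π/(4 ln2))`.
4. **Assignment and abundances** — fitted centers are mapped to motifs by
   literature wavenumber windows (side chains 1602–1614, aromatic ring
   1615–1640, unordered 1641–1652, α-helix 1653–1669, β-sheet 1670–1682,
   β-turn 1683–1700 cm⁻¹, with per-band overrides), and each motif's
   abundance is reported as 100 × (its band area) / (total fitted area).
5. **Trend** — per-motif abundance series across exposure time, with first
   differences.

Because no raw spectra are deposited with the study this package follows,
it ships a synthetic-spectrum generator (`amide_preset()` /
`generate_spectrum()`) that rebuilds each group's averaged amide-I spectrum
from the published band centers and abundance percentages, plus optional
fluorescence baseline, noise and cosmic-ray spikes. All synthetic data are
labelled as such in their metadata.

## Worked example

Recover the published control-group deconvolution from its own synthetic
spectrum:

```r
library(amideR)

spec <- amide_preset("control")           # 5 published bands, FWHM 20
s <- preprocess(generate_spectrum(spec),
                preprocess_config(baseline_method = "none",
                                  stages = c("smooth", "crop")))
res <- deconvolve_spectrum(s, fit_config(center_seeds = spec$meta$center_seeds))
res
#> <deconvolution_result> 5 bands on [1590, 1710] cm^-1, R^2 = 1.0000
#>   band 1: center 1607.99, fwhm 19.99, area 0.09979  [side_chain]
#>   band 2: center 1621.98, fwhm 20.05, area 0.05027  [aromatic_ring]
#>   band 3: center 1642.00, fwhm 19.99, area 0.09989  [unordered]
#>   band 4: center 1665.00, fwhm 20.00, area 0.6001  [alpha_helix]
#>   band 5: center 1685.00, fwhm 20.00, area 0.1499  [beta_turn]
#>   abundance (%): side_chain=10, aromatic_ring=5, unordered=10, alpha_helix=60, beta_turn=15
```

The recovered abundances (10 / 5 / 10 / 60 / 15 %) equal the generating
ones; the α-helix band sits at 1665 cm⁻¹. The same round trip over all six
exposure groups is the `analysis/` workflow:

```sh
Rscript analysis/01_simulate.R    # write the synthetic per-group spectra
Rscript analysis/02_deconvolve.R  # fit all groups, write the band table
Rscript analysis/03_trend.R       # abundance-vs-exposure-day trend
```

Stage 3 prints the headline result: α-helix falls monotonically
(60 → 47 → 46 → 41 → 22 → 20 %) while β-sheet is absent through 30 days and
dominant (52 / 48 %) at 60 and 90 days.

## Package layout

- `R/` — spectrum containers and I/O, preprocessing chain, deconvolution
  core, assignment/trend, synthetic generator, pipeline orchestration.
- `analysis/` — the numbered workflow drivers shown above.
- `tests/testthat/` — unit, property and acceptance suites (oracle-based:
  analytic second derivatives, generator ground truth, closed-form areas).
- `vignettes/amide-deconvolution.Rmd` — methods notes: model, assumptions,
  parameter choices, numerical behavior and limitations.
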