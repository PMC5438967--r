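---
title: "Amide I band deconvolution: model, parameters and numerical behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amide I band deconvolution: model, parameters and numerical behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amideR)
```

## The model

A point Raman spectrum of tissue in the amide I region is modelled as

$$ y(\nu) \;=\; \sum_{j=1}^{k} a_j \exp\!\left(-4\ln 2\,
\frac{(\nu - c_j)^2}{w_j^2}\right) \;+\; b(\nu) \;+\; \varepsilon(\nu), $$

a sum of $k$ Gaussian sub-bands (center $c_j$ in cm⁻¹, FWHM $w_j$,
amplitude $a_j \ge 0$) over a smooth fluorescence baseline $b$ and noise
$\varepsilon$, with occasional one-pixel cosmic-ray spikes. Each sub-band's
area, $A_j = a_j w_j \sqrt{\pi/(4\ln 2)}$, is computed in closed form and —
to first approximation — taken as proportional to the abundance of the
backbone motif that vibrates at $c_j$. Abundances are therefore reported as
$100\,A_j / \sum_i A_i$ over the fit region.

Assumptions worth stating explicitly:

* **Pure Gaussian line shapes.** Tissue amide-I components are broad and
  inhomogeneously broadened, which favours Gaussian over Lorentzian/Voigt
  profiles; no alternative shape is offered in this version.
* **Area ∝ abundance.** This ignores motif-dependent Raman cross sections;
  it is the standard first-order reading of amide-I deconvolutions and the
  one the abundance numbers here inherit.
* **Additive smooth baseline**, separable from the bands by curvature.

## The pipeline and its order

Preprocessing runs in a fixed order: despike → baseline → vector-normalize →
average → Savitzky–Golay smooth → crop. Despiking must precede averaging
(one spike would survive a 30-spectrum mean attenuated but present);
normalization precedes averaging so every acquisition contributes equally;
smoothing operates on the averaged trace; cropping comes last so that
edge effects of the smoother fall outside the analysis window. Every stage
can be disabled individually — data that arrive already baseline-corrected
(as vendor-exported tissue spectra typically do) use `baseline_method =
"none"`, and a second light baseline pass before deconvolution remains
available through the same switch.

The crop default is 1590–1710 cm⁻¹, deliberately wider than the 1600–1700
amide I core: the side-chain (~1604) and aromatic-ring (~1612) shoulder
bands are not baseline-separated from the amide I envelope, so they must be
inside the fit region or their tails would corrupt the 1620–1640 area.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `despike_z` | 8 | – | modified z-score threshold; spikes are 10–100× the local scale, real band curvature stays below ~1 |
| `despike_window` | 5 | points | one–two pixel artifacts vs ≥8-point bands |
| `sg_window`, `sg_polyorder` | 5, 2 | points, – | five-point quadratic smoother; order 2 preserves band height to ≪1% at FWHM ≥ 20 on a 1 cm⁻¹ grid |
| `crop_lo`, `crop_hi` | 1590, 1710 | cm⁻¹ | see above |
| `fwhm_bounds` | 8–45 | cm⁻¹ | narrower than 8 is an unresolved spike, wider than 45 would span two motif windows |
| `center_window` | ±6 | cm⁻¹ | allows the observed center drift across groups (α-helix 1665→1652) without letting bands swap windows |
| `min_band_separation` | 8 | cm⁻¹ | second-derivative minima closer than this are one distorted lobe, not two bands |
| preset `fwhm` | 20 | cm⁻¹ | typical amide-I component width; no width is published for the study bands, so every width-dependent tolerance is defined against this default |

## Band counting: what the second derivative can and cannot do

The number of sub-bands is taken from the negative-lobe minima of the
Savitzky–Golay second derivative. For well-separated components this is
reliable and matches an analytic-derivative root-finding oracle to within
one grid step (tested). Its resolution limit is intrinsic, not numerical:
two Gaussians of FWHM 20 separated by less than roughly 0.7×FWHM produce a
single second-derivative minimum, and no minima-counting scheme can see
both. Several published group inventories contain such pairs (e.g. adjacent
bands 11 cm⁻¹ apart), so the automatic count cannot reproduce them. For
exactly this case `fit_config(center_seeds = ...)` accepts an explicit
inventory — the round-trip analyses seed the fit with each group's known
band centers, which is also how the original analysis was specified (the
band count was fixed per group before fitting). When a seeded pair is
genuinely unresolvable the fitter still returns a well-defined answer: one
band carrying the pair's combined area (tested to 3%).

## Fitting: determinism and multimodality

Multi-Gaussian least squares is multimodal. The fitter therefore runs
bounded Levenberg–Marquardt from a fixed grid of eight trial widths spanning
`fwhm_bounds`, with starting amplitudes obtained from the linear
least-squares subproblem at each width, and keeps the converged solution
with the lowest deviance. All starts are deterministic — there is no random
initialization anywhere in the package; the only randomness lives in the
synthetic generator's explicit seed — so two runs on identical input are
bit-identical (tested). A single midpoint-width start was tried first and
abandoned: on the five-band control inventory it converged to a local
minimum ~1 percent point off in abundance.

## Baseline estimation

Two estimators are exposed. The default, asymmetric least squares (a
Whittaker smoother whose weights are `p` above the current baseline and
`1 − p` below), is the standard choice for the broad fluorescence humps of
tissue Raman; its smoothness penalty, however, resists genuine baseline
curvature, so on a strongly cubic background its bias can reach tens of
percent of peak height (bounded and tested). The polynomial method fits a
degree-`baseline_order` polynomial by iterating "fit, then re-clip the
*original* signal at fit + RMS-residual". Re-clipping from the original
signal rather than the previous iterate matters: the classic clip-only
iteration permanently corrupts any baseline-only stretch an early fit
undercuts. The polynomial method is exact on inputs that are polynomials of
its degree and recovers a known cubic under two amide bands to 2% of peak
height — provided it is given a region wide enough to contain baseline-only
stretches on both sides (the tests use 1500–1800 cm⁻¹). Estimating a
flexible baseline from inside the 1590–1710 window alone is ill-posed, which
is why baseline correction belongs before cropping in the chain.

## Assignment windows and overrides

The default scheme is the literature windows: side chains 1602–1614,
aromatic ring 1615–1640, unordered 1641–1652, α-helix 1653–1669, β-sheet
1670–1682, β-turn 1683–1700 cm⁻¹. The β-turn window is extended to 1700
because oxidative exposure displaces turn bands to 1690–1695. Centers in
inter-window gaps take the nearest edge (ties to the lower window); centers
more than 10 cm⁻¹ outside every window are `unassigned`.

Windows alone cannot encode group context: early in the exposure series a
band near 1680 cm⁻¹ is a displaced β-turn, while later the same wavenumber
hosts the emerging β-sheet; likewise an α-helix band pushed down to
1652 cm⁻¹ lands on the unordered window's edge. `default_overrides()` ships
the four documented exceptions (7-day 1615 → side chain; 15-day 1681 and
30-day 1680 → β-turn; 60-day 1652 → α-helix), and arbitrary per-band
overrides can be supplied per group. Without overrides the windows agree
with the published per-group assignments on 24 of 28 bands; with them, on
all 28.

## What the synthetic generator does and does not emulate

`generate_spectrum()` reproduces: Gaussian sub-band mixtures with exact area
ratios (total clean area 1), a polynomial fluorescence baseline, white
Gaussian noise scaled to the clean maximum, and Poisson-count one-pixel
spikes — each part seeded and reproducible, with the clean trace retained
for oracle tests. It does **not** emulate: non-Gaussian band character,
wavenumber-correlated noise, detector etaloning, photobleaching drift
across the 30 acquisitions, or neighbouring lipid/nucleic-acid bands
outside 1590–1710 cm⁻¹. Passing round trips therefore validate the
numerical chain — they show the pipeline recovers known parameters through
its own preprocessing — but they cannot certify accuracy on real tissue,
where line shapes and backgrounds violate the generative model to an
unknown degree.

Generator defaults mirror the study conditions: grid 1590–1710 cm⁻¹ at
1 cm⁻¹ (the instrument resolved 4 cm⁻¹; `grid = c(1590, 1710, 4)` gives
instrument-realistic sampling), component FWHM 20 cm⁻¹, 30 spectra per
section when sets are simulated, preset centers/areas exactly as published.

## Numerical choices and degenerate inputs

* Despike scale is floored at 1% of the intensity range so noiseless smooth
  spectra (detail MAD ≈ 0) are never flagged; the operation is idempotent.
* Vector normalization refuses all-zero spectra; averaging refuses
  mismatched grids (resample first, by linear interpolation).
* The smoother and the second derivative require a uniform grid and say so.
* Fits refuse fewer than 3 points per free parameter and seeds outside the
  region; non-convergence raises an error carrying the best-so-far fit.
* Percent abundances are kept at full precision internally and rounded only
  at serialization/report time.
* Candidate merging keeps the deeper second-derivative lobe; ties keep the
  lower-wavenumber candidate (sorted processing order).

## Problem sizes

All analyses here run on single averaged spectra of 121 points (1590–1710
at 1 cm⁻¹) with 3–5 bands (9–15 free parameters), and the Monte-Carlo noise
checks use 20 seeds at 1% noise; each fit takes milliseconds, the whole
suite a few seconds.

## Known limitations

* Area-proportional abundances ignore differential Raman cross sections.
* Pure Gaussian shapes only; no Voigt option.
* The automatic band count cannot resolve components closer than ~0.7 FWHM
  (use explicit seeds).
* ALS baselines are biased on strongly curved backgrounds; prefer the
  polynomial method when the background family is known.
* True component widths of the study's tissue bands are unknown; all
  width-dependent tolerances are defined against the 20 cm⁻¹ preset.
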