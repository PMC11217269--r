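---
title: "Methods: single-cell FTIR profiling of sea-ice algae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell FTIR profiling of sea-ice algae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icephenome)
```

## The problem and the model

Sea-ice microalgae provision polar food webs in early spring, and their
nutritional quality is set by their biomolecular makeup — the balance of
lipids, proteins, carbohydrates and, in diatoms, biogenic silica. A
mid-infrared absorbance spectrum of a single hydrated cell carries that
makeup as a set of diagnostic bands: CH-stretch bands of unsaturated
(~3011 cm⁻¹) and saturated (~2921, ~2852 cm⁻¹) fatty acids, the lipid
ester carbonyl (~1744 cm⁻¹), protein amide II (~1549 cm⁻¹), carboxylates
(~1400 cm⁻¹), phosphodiesters (~1241 cm⁻¹), carbohydrates (1146–1191
cm⁻¹) and silica (~1080 cm⁻¹). Under the Beer–Lambert law, the absorbance
contributed by each constituent is proportional to its concentration at
fixed path length, so the integrated area under an assigned band is a
relative concentration measure.

The quantification chain implemented here is the standard chemometric
sequence:

1. **Savitzky–Golay smoothing + second derivative** (9-point window,
   cubic polynomial, one least-squares pass): sharpens overlapping bands
   and annihilates constant and linear baseline components.
2. **Standard Normal Variate (SNV)**: per-spectrum centring to mean 0 and
   scaling to unit sample standard deviation, removing multiplicative
   path-length/cell-thickness differences between spectra.
3. **Band-area integration**: trapezoidal integration of the rectified
   second-derivative signal over each registry window, averaged over the
   measurement points of a cell, log₁₀-transformed for analysis (a
   Shapiro–Wilk screen decides the transform per band).

Around this spectral core sit the environmental computations used in
seasonal sea-ice studies (brine physics, albedo, nutrient stoichiometry
against the amended Redfield reference 106C:16N:15Si:1P), fatty-acid
class accounting over "C:D n-x" nomenclature, and self-implemented
multivariate statistics (PCA, redundancy analysis and ANOSIM with
Monte-Carlo permutation tests).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| SG `half_window` | 4 | samples | "4 points either side": a 9-point window at 4 cm⁻¹ spacing |
| SG `polyorder` | 3 | – | cubic local fit; exact for polynomials up to degree 3 |
| SNV range | CH-stretch ∪ fingerprint | cm⁻¹ | normalisation reflects the analysed signal, not the silent 2800–1770 gap; full-range is selectable |
| band windows | ±15 (CH region), ±25 (fingerprint) | cm⁻¹ | band centres are nominal ("~"); widths chosen to cover condensed-phase bandwidths without overlap; carbohydrate fixed at 1146–1191 |
| rectification | negative-lobe clip | – | second-derivative peaks are negative-lobed; clipping the positive side-lobes is the nonnegative choice that stays linear in amplitude |
| brine validity | −22.9 ≤ T < 0 | °C | domain of the Frankenstein–Garner relation Sb = 1000/(1 − 54.11/T) |
| N threshold | 1 | µM NOₓ | conservative "potentially limiting" level (≈0.6 µM is observed at season's end); configurable |
| permutations | 999 | – | add-one convention p = (1+more extreme)/(1+N), so p is never 0 |

## What the synthetic generator emulates — and what it does not

Measured single-cell spectra are emulated as sums of unit-height
Gaussians (one per registry band, height = concentration "amount", so
each injected peak has closed-form area amount·σ·√2π) over a cubic
polynomial baseline in a scaled coordinate, plus iid Gaussian noise.
Defaults state the world being simulated:

- peak widths 8 cm⁻¹ (CH region) and 12 cm⁻¹ (fingerprint), typical of
  condensed-phase bands and resolvable by the 9-point filter;
- noise sd 0.003 absorbance ≈ 0.5% of the peak signal of the default
  composition;
- cohorts of ~26 cells per site (the campaign-scale sampling mean), 3
  points per cell (a stand-in — real aperture counts are not reported),
  between-cell coefficient of variation 0.1;
- a default composition with protein and carbohydrate dominant, moderate
  lipid and silica — a nutrient-replete diatom.

Not modelled: Mie/resonant-Mie scattering (the measurement protocol
avoided it by probing hydrated cells), instrument line-shape convolution,
detector noise spectra, atmospheric CO₂/H₂O features. A green test
therefore establishes that the chain recovers known injected
compositions under additive noise and smooth baselines; it does not
establish robustness to scattering artefacts, which real data may
contain.

The environment generator draws ice temperature in [−10, −0.5] °C and
bulk salinity in [2 ppt, min(15, 0.8·Sb(T))] — the cap keeps the implied
brine state physical (brine volume below 100%) for warm ice, where an
unconstrained draw could exceed the equilibrium brine salinity.

## Numerical choices

- **Derivative scaling.** The SG second derivative is scaled by 1/h²
  (h = grid spacing) so values carry physical units; only ratios matter
  downstream, but this makes closed-form cross-checks direct.
- **Edges.** The `half_window` samples at each end are dropped; no
  extrapolation. All registry bands are interior on a 4000–800 cm⁻¹
  grid.
- **Filter attenuation.** A 9-point cubic filter at 4 cm⁻¹ spacing
  attenuates the peak curvature of a σ = 8 cm⁻¹ Gaussian to ≈ 0.42 of
  its analytic value. The filter is linear and time-invariant, so the
  attenuation is strictly proportional: Beer–Lambert linearity, band
  ratios and ground-truth closure are unaffected, but absolute areas are
  estimator-specific. Tests therefore validate the implementation
  against a brute-force local-polynomial oracle at the stated widths and
  against analytic quadrature only for wide (σ = 80 cm⁻¹) bands where
  the bias is negligible.
- **Where amounts are linear.** SNV is scale-invariant per spectrum, so
  an absolute injected-amount ratio is only recoverable *before*
  normalisation. Quantitative closure checks (linearity, two-group
  effect recovery) integrate at the derivative stage
  (`normalize = FALSE`); the multivariate analyses consume the
  SNV-normalised areas, which measure composition relative to the
  cell's overall signal — the quantity the seasonal comparisons need.
- **Brine physics tolerance.** The printed brine salinities were
  evidently computed from unrounded temperatures (back-solving gives
  e.g. T = −2.4993 for a printed −2.5 row); from 1-decimal printed
  temperatures the attainable agreement is two units in the second
  decimal, which is the packaged-table tolerance. The density-ratio
  brine-volume form (ρ_ice = 917 kg/m³, ρ_brine = 1000 + 0.8·Sb)
  reproduces all printed values within ±1 percentage point; the
  Cox–Weeks phase-relation polynomial is available as an alternative.
- **Fatty-acid totals.** Class sums are exact sums of displayed rows.
  Printed totals that disagree beyond rounding (acids under 0.1% are not
  displayed) are reported by `fa_reconciliation()` with the difference —
  never silently corrected.
- **Degenerate inputs.** Zero-variance spectra refuse SNV; groups with a
  single member refuse ANOSIM; rank-deficient predictor matrices refuse
  RDA and name the collinear columns; exact fits report F as `Inf`
  rather than overflowing.

## Design decisions that were genuinely open

- **Gaussian lineshape** for synthetic bands (no lineshape is stated for
  the real instrument); Lorentzian wings would only widen the documented
  cross-talk margins.
- **SNV after cropping** to the analysis range (CH ∪ fingerprint); the
  alternative (full acquisition range) is one switch away and changes
  only the per-spectrum scale factor.
- **Cell aggregation by the mean** over measurement points (sum would
  confound point count with content).
- **Bray–Curtis** as the community dissimilarity for ANOSIM (the
  conventional companion for abundance data); Euclidean is available by
  passing a different matrix.
- **Forward selection** for RDA "model optimisation": candidates ranked
  by added constrained variance, retained at permutation p < 0.05 —
  mirroring the practice of displaying only significant vectors.
- **ANOSIM null calibration bound.** Under a calibrated null,
  P(p > 0.05) = 0.95 per repeat *by construction*, so a 100-repeat
  simulation is tested against the binomial 99% lower bound (88/100),
  not against 95/100, which the expected count itself would fail about
  half the time.

## Known limitations

- Absolute band areas are estimator-specific (filter attenuation);
  only relative comparisons are meaningful, which is how they are used.
- The carbohydrate window (1146–1191 cm⁻¹) abuts the silica band's
  neighbourhood; the registry warns when edited windows overlap by more
  than 25%. Published sources are themselves ambiguous about a "silica
  peak at 1150 cm⁻¹" versus the ~1080 cm⁻¹ assignment; the registry
  follows the tabulated ~1080 and does not reconcile the two.
- Brine relations are equilibrium formulae; they do not model drainage
  dynamics or granular/columnar microstructure.
- The RDA per-predictor variance attribution reports marginal and
  conditional fractions from forward selection; published "% explained"
  splits without a stated partitioning method are not reproduced.

## A worked example

```{r example, eval = FALSE}
design <- cohort_design(
  groups = list(
    list(site = "outer", week = "Week 1", n_cells = 26),
    list(site = "outer", week = "Week 6", n_cells = 26,
         composition = local({
           c <- default_cell_composition()
           c["lipid_ester_carbonyl"] <- 2 * c["lipid_ester_carbonyl"]; c
         }))),
  seed = 1)
cohort <- generate_cohort(design)
pre <- lapply(cohort$spectra, preprocess_spectrum)
profiles <- profile_cells(pre)
pca_ordination(as.matrix(profiles[grep("^log10_", names(profiles))]))
```

The packaged reference tables and every registered numeric target are
recomputed by `reproduce_paper()`; the same quantities are asserted in
`tests/testthat/test-acceptance.R` and exported by
`scripts/acceptance.R`.
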