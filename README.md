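# icephenome

Single-cell infrared phenotyping of sea-ice algae, with the
environmental and statistical machinery a seasonal sea-ice study needs.

## What problem this solves, and for whom

Sea-ice diatoms feed polar food webs in spring; how nutritious they are
depends on their biomolecular makeup — lipid, protein, carbohydrate and
silica content — which shifts as the ice warms, brine drains and
nitrogen runs out. FTIR microspectroscopy measures that makeup cell by
cell: each biomolecule class absorbs at diagnostic mid-infrared bands,
and under the Beer–Lambert law (absorbance ∝ concentration at fixed path
length) the integrated area under an assigned band is a relative
concentration measure.

This package is for ecophysiologists and chemometricians who need that
pipeline end to end, reproducibly:

- **Spectral chain** — Savitzky–Golay smoothing + second derivative
  (9-point window, cubic), Standard Normal Variate normalisation, and
  band-area integration over a curated nine-band registry
  (unsaturated/saturated fatty-acid CH stretches at ~3011/2921/2852
  cm⁻¹, ester carbonyl ~1744, amide II ~1549, carboxylate ~1400,
  phosphodiester ~1241, carbohydrate 1146–1191, silica ~1080).
- **Sea-ice physics** — brine salinity Sb(T) = 1000/(1 − 54.11/T),
  brine volume fraction (S_bulk/Sb)·(ρ_ice/ρ_brine)·100, PAR albedo.
- **Nutrient stoichiometry** — molar N:Si and Si:P with limitation flags
  against the silicate-amended Redfield reference 106C:16N:15Si:1P.
- **Fatty-acid accounting** — a "C:D n-x" nomenclature parser and
  SAFA/MUFA/PUFA, omega-series, EPA+DHA class sums.
- **Statistics** — self-implemented PCA, redundancy analysis (RDA) with
  Monte-Carlo permutation tests and forward model selection, ANOSIM
  (with automatic exhaustive enumeration on small designs), Bray–Curtis
  dissimilarity, and OLS regression with F/R² reporting.
- **Synthetic data** — a generator of single-cell spectra (Gaussian band
  mixtures over a polynomial baseline, seeded noise), cohorts with known
  ground truth, and environmental/community tables, so every stage is
  testable without instrument access.

## Worked example

Simulate a two-cohort campaign in which end-of-season cells double their
lipid ester-carbonyl content, then recover that effect:

```r
library(icephenome)

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

# quantitative closure: integrate at the derivative stage
pre  <- lapply(cohort$spectra, preprocess_spectrum, normalize = FALSE)
prof <- profile_cells(pre)
m <- tapply(prof$area_lipid_ester_carbonyl, prof$week, mean)
m[["Week 6"]] / m[["Week 1"]]
#> [1] 1.922
```

The injected 2.0× lipid effect is recovered as 1.922 (26 cells/group,
10% between-cell variation, 0.5% noise). The environmental helpers
reproduce published reference values directly:

```r
brine_salinity(-2.1)            # ppt, from ice temperature
#> [1] 37.3599
brine_volume_fraction(10.80, -2.3)   # % of ice volume
#> [1] 23.52239

fa <- fatty_acid_table()
fa_class_sums(fa$fa_name, fa$outer_pct)[c("mufa", "pufa", "epa_plus_dha")]
#> $mufa: 54   $pufa: 16   $epa_plus_dha: 7.8
```

`reproduce_paper()` recomputes all 12 registered reference quantities
from the packaged tables and reports pass/fail at each one's tolerance:

```r
head(reproduce_paper(), 3)
#>                            id computed printed tolerance pass
#> 1     brine_salinity_w1_inner 37.35990   37.36      0.01 TRUE
#> 2 inner_brine_volume_mean_pct 24.06574   24.00      0.50 TRUE
#> 3    outer_bulk_salinity_mean 10.06250   10.10      0.05 TRUE
```

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "icephenome.R", package = "icephenome"))')" \
    simulate --out synthetic --seed 1
# also: preprocess, quantify, stats, run --config run.dcf, reproduce-paper
```

Pipeline runs are configured by a DCF (`key: value`) file and are
byte-identical under a fixed config + seed; every output CSV carries a
provenance header with the seed and config hash.

## Further reading

`vignettes/icephenome-methods.Rmd` documents the model and its
assumptions, the tunable parameters, what the synthetic generator does
and does not emulate, the numerical choices (derivative scaling, filter
attenuation, rectification, tolerances) and known limitations.
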