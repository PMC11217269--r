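Package: icephenome
Title: Single-Cell FTIR Biomolecular Profiling of Sea-Ice Algae with
    Brine Physics, Fatty-Acid Accounting and Permutation Statistics
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the biomolecular content (lipid,
    protein, carbohydrate, silica) of individual microalgal cells from
    Fourier-transform infrared (FTIR) microspectra, together with the
    environmental computations used in seasonal sea-ice studies.
    Implements the chemometric chain of Savitzky-Golay second-derivative
    transformation, Standard Normal Variate normalization and
    Beer-Lambert band-area integration over a curated infrared band
    registry; sea-ice brine salinity and brine-volume physics; nutrient
    stoichiometry against the silicate-amended Redfield reference
    (106C:16N:15Si:1P); fatty-acid nomenclature parsing with
    SAFA/MUFA/PUFA and omega-series class sums; and self-contained
    multivariate statistics (PCA, redundancy analysis and ANOSIM with
    Monte-Carlo permutation tests, Bray-Curtis dissimilarity, univariate
    regression). A synthetic-data module generates single-cell spectra
    and environmental tables with known ground truth so the whole
    pipeline is testable without instrument access.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
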