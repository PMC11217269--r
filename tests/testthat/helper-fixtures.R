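# Shared builders for synthetic fixtures; everything is generated in code.

the_registry <- default_band_registry()

# single-band raw spectrum on the default grid, no baseline unless asked
single_band_spectrum <- function(band, amount = 1, noise_sd = 0, seed = 1L,
                                 baseline = 0, sigma = NULL) {
  comp <- data.frame(band_name = band, amount = amount)
  if (!is.null(sigma)) comp$peak_sigma <- sigma
  generate_cell_spectrum(comp, baseline_coefficients = baseline,
                         noise_sd = noise_sd, seed = seed)
}

# derivative-stage (un-normalized) band area of a single injected band
derivative_area <- function(band, amount = 1, ...) {
  s <- single_band_spectrum(band, amount, ...)
  integrate_band(preprocess_spectrum(s, normalize = FALSE), band, the_registry)
}

# two-group cohort with one band's amount scaled in the second group
two_group_design <- function(band = "lipid_ester_carbonyl", factor = 2,
                             n_cells = 10L, cv = 0, noise_sd = 0,
                             points_per_cell = 1L, seed = 1L) {
  comp2 <- default_cell_composition()
  comp2[band] <- factor * comp2[band]
  cohort_design(
    groups = list(
      list(site = "outer", week = "W1", n_cells = n_cells, cv = cv),
      list(site = "outer", week = "W6", n_cells = n_cells, cv = cv,
           composition = comp2)),
    noise_sd = noise_sd, points_per_cell = points_per_cell, seed = seed)
}

# group-mean area ratio (week W6 over W1) for one band, derivative stage
recovered_ratio <- function(design, band = "lipid_ester_carbonyl") {
  cohort <- generate_cohort(design)
  pre <- lapply(cohort$spectra, preprocess_spectrum, normalize = FALSE)
  prof <- profile_cells(pre, the_registry)
  m <- tapply(prof[[paste0("area_", band)]], prof$week, mean)
  unname(m[["W6"]] / m[["W1"]])
}

# analytic second derivative of a unit-height Gaussian
gaussian_d2 <- function(x, centre, sigma)
  ((x - centre)^2 / sigma^4 - 1 / sigma^2) * exp(-(x - centre)^2 / (2 * sigma^2))
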