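#' Default acquisition grid
#'
#' 4000 -> 800 cm^-1 at 4 cm^-1 resolution, in acquisition (descending)
#' order: 801 samples.
#'
#' @return numeric vector of wavenumbers.
#' @export
default_grid <- function() seq(4000, 800, by = -4)

#' Default Gaussian peak width for a band
#'
#' 8 cm^-1 in the CH-stretch region (centre > 2000 cm^-1), 12 cm^-1 in
#' the fingerprint region: widths typical of condensed-phase infrared
#' bands, broad enough that a 9-point derivative filter at 4 cm^-1
#' resolution resolves them without distortion.
#'
#' @param centre band centre(s) in cm^-1.
#' @return numeric sigma(s) in cm^-1.
#' @export
default_peak_sigma <- function(centre) ifelse(centre > 2000, 8, 12)

#' Default per-cell biomolecular composition
#'
#' Band amounts (Gaussian peak heights, arbitrary concentration units)
#' for a nutrient-replete diatom-like cell: protein and carbohydrate
#' dominant, moderate lipid and silica, smaller nucleic-acid and
#' carboxylate contributions. Used as the baseline composition that group
#' effects in cohort designs perturb.
#'
#' @return named numeric vector over the default registry bands.
#' @export
default_cell_composition <- function() {
  c(fa_unsaturated = 0.15, fa_saturated_ch2_asym = 0.35,
    fa_saturated_ch2_sym = 0.25, lipid_ester_carbonyl = 0.30,
    protein_amide_ii = 0.60, carboxylate = 0.25, phosphodiester = 0.20,
    carbohydrate = 0.50, silica = 0.45)
}

#' Normalise a composition argument to (band_name, amount, peak_sigma)
#' @keywords internal
as_composition <- function(composition, registry) {
  if (is.numeric(composition) && !is.null(names(composition)))
    composition <- data.frame(band_name = names(composition),
                              amount = as.numeric(composition),
                              stringsAsFactors = FALSE)
  stopifnot(is.data.frame(composition),
            all(c("band_name", "amount") %in% names(composition)))
  unknown <- setdiff(composition$band_name, registry$name)
  if (length(unknown))
    stop_("unknown band(s) in composition: %s", paste(unknown, collapse = ", "))
  if (any(composition$amount < 0)) stop_("band amounts must be >= 0")
  if (is.null(composition$peak_sigma)) {
    ctr <- registry$centre[match(composition$band_name, registry$name)]
    composition$peak_sigma <- default_peak_sigma(ctr)
  }
  if (any(composition$peak_sigma <= 0)) stop_("peak_sigma must be > 0")
  composition
}

#' Evaluate the baseline polynomial
#'
#' Coefficients (ascending powers, degree <= 3) apply to the scaled
#' coordinate u = (v - mid) / span, u in [-1/2, 1/2] over the grid, so
#' that O(1) coefficients give O(1) baselines regardless of the
#' wavenumber scale.
#'
#' @param coefficients numeric vector, length <= 4.
#' @param grid wavenumber grid.
#' @return baseline values on the grid.
#' @export
baseline_polynomial <- function(coefficients, grid) {
  if (length(coefficients) > 4L)
    stop_("baseline polynomial degree must be <= 3 (got %d coefficients)",
          length(coefficients))
  if (length(coefficients) == 0L) return(rep(0, length(grid)))
  u <- (grid - mean(range(grid))) / diff(range(grid))
  out <- rep(0, length(grid))
  for (k in seq_along(coefficients)) out <- out + coefficients[k] * u^(k - 1L)
  out
}

#' Generate one synthetic point spectrum
#'
#' Absorbance is a sum of unit-height Gaussians (one per band, height =
#' `amount`, so the analytic area of each injected peak is
#' `amount * sigma * sqrt(2*pi)`), a slowly varying polynomial baseline,
#' and iid Gaussian noise. Emulates Beer-Lambert behaviour: absorbance
#' contributions add linearly in concentration.
#'
#' @param composition named numeric vector of band amounts, or a data
#'   frame with `band_name`, `amount` and optionally `peak_sigma`.
#' @param baseline_coefficients see [baseline_polynomial()].
#' @param noise_sd iid noise standard deviation in absorbance units.
#' @param grid strictly monotone wavenumber grid covering every band
#'   window.
#' @param seed integer seed (same inputs + same seed => identical output).
#' @param registry band registry.
#' @param point_id,cell_id,site,week metadata for the spectrum.
#' @return a raw-stage `ir_spectrum`.
#' @export
generate_cell_spectrum <- function(composition,
                                   baseline_coefficients = c(0.05, 0.02, 0.01, 0.005),
                                   noise_sd = 0.003,
                                   grid = default_grid(),
                                   seed = 1L,
                                   registry = default_band_registry(),
                                   point_id = "p1", cell_id = "c1",
                                   site = NA_character_, week = NA_character_) {
  if (length(grid) == 0L) stop_("empty wavenumber grid")
  if (noise_sd < 0) stop_("noise_sd must be >= 0")
  comp <- as_composition(composition, registry)
  rng <- range(grid)
  for (i in seq_len(nrow(comp))) {
    e <- band_entry(registry, comp$band_name[i])
    if (e$window_lo < rng[1] || e$window_hi > rng[2])
      stop_("band '%s' lies outside the grid range [%s, %s]",
            comp$band_name[i], rng[1], rng[2])
  }
  y <- baseline_polynomial(baseline_coefficients, grid)
  for (i in seq_len(nrow(comp))) {
    ctr <- registry$centre[match(comp$band_name[i], registry$name)]
    y <- y + comp$amount[i] * exp(-(grid - ctr)^2 / (2 * comp$peak_sigma[i]^2))
  }
  if (noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(length(grid), sd = noise_sd))
  ir_spectrum(grid, y, point_id = point_id, cell_id = cell_id,
              site = site, week = week, stage = "raw")
}

#' Describe a synthetic measurement cohort
#'
#' A cohort design is a list of groups (site x week cohorts) with a cell
#' count, a mean composition and a between-cell coefficient of variation,
#' plus acquisition-level parameters. Defaults mirror a single-cell
#' campaign of ~26 cells per site measured at 3 points per cell with
#' noise at ~0.5% of the peak signal.
#'
#' @param groups list of lists, each with `site`, `week`, `n_cells`,
#'   `composition` (named numeric, defaults to
#'   [default_cell_composition()]) and `cv` (between-cell coefficient of
#'   variation, default 0.1).
#' @param noise_sd absorbance-unit noise (default 0.003).
#' @param baseline_coefficients baseline polynomial (degree <= 3).
#' @param points_per_cell point spectra per cell (default 3).
#' @param seed integer master seed.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(groups, noise_sd = 0.003,
                          baseline_coefficients = c(0.05, 0.02, 0.01, 0.005),
                          points_per_cell = 3L, seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  groups <- lapply(groups, function(g) {
    g$composition <- g$composition %||% default_cell_composition()
    g$cv <- g$cv %||% 0.1
    if (is.null(g$n_cells) || g$n_cells < 1L)
      stop_("each group needs n_cells >= 1")
    if (g$cv < 0) stop_("coefficient of variation must be >= 0")
    if (is.null(g$site) || is.null(g$week)) stop_("each group needs site and week labels")
    g
  })
  if (noise_sd < 0) stop_("noise_sd must be >= 0")
  if (points_per_cell < 1L) stop_("points_per_cell must be >= 1")
  structure(list(groups = groups, noise_sd = noise_sd,
                 baseline_coefficients = baseline_coefficients,
                 points_per_cell = as.integer(points_per_cell),
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Generate a cohort of synthetic cell spectra with ground truth
#'
#' Each cell draws its band amounts from the group mean composition with
#' the group's between-cell CV (normal, truncated at zero); all point
#' spectra of a cell share its amounts and differ only in acquisition
#' noise. The ground-truth table records the exact injected amount per
#' cell and band, which downstream closure tests compare against
#' pipeline-recovered areas.
#'
#' @param design a [cohort_design()].
#' @param registry band registry.
#' @param grid wavenumber grid.
#' @return list with `spectra` (list of raw `ir_spectrum`) and `truth`
#'   (data frame: cell_id, site, week, band, amount).
#' @export
generate_cohort <- function(design, registry = default_band_registry(),
                            grid = default_grid()) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(design$seed, {
    spectra <- list()
    truth <- list()
    cell_no <- 0L
    for (gi in seq_along(design$groups)) {
      g <- design$groups[[gi]]
      comp <- as_composition(g$composition, registry)
      for (ci in seq_len(g$n_cells)) {
        cell_no <- cell_no + 1L
        cid <- sprintf("cell%03d", cell_no)
        amounts <- pmax(0, comp$amount * (1 + g$cv * stats::rnorm(nrow(comp))))
        truth[[length(truth) + 1L]] <- data.frame(
          cell_id = cid, site = g$site, week = g$week,
          band = comp$band_name, amount = amounts, stringsAsFactors = FALSE)
        cell_comp <- comp
        cell_comp$amount <- amounts
        for (pi in seq_len(design$points_per_cell)) {
          pid <- sprintf("%s_pt%d", cid, pi)
          y <- baseline_polynomial(design$baseline_coefficients, grid)
          for (i in seq_len(nrow(cell_comp))) {
            ctr <- registry$centre[match(cell_comp$band_name[i], registry$name)]
            y <- y + cell_comp$amount[i] *
              exp(-(grid - ctr)^2 / (2 * cell_comp$peak_sigma[i]^2))
          }
          if (design$noise_sd > 0)
            y <- y + stats::rnorm(length(grid), sd = design$noise_sd)
          spectra[[length(spectra) + 1L]] <- ir_spectrum(
            grid, y, point_id = pid, cell_id = cid,
            site = g$site, week = g$week, stage = "raw")
        }
      }
    }
    list(spectra = spectra, truth = do.call(rbind, truth))
  })
}

#' Generate a physically plausible synthetic ice-core table
#'
#' Draws site x date environmental records within the ranges typical of
#' spring land-fast sea ice: ice temperature in [-10, -0.5] degC, bulk
#' salinity in [2, 15] ppt, nonnegative nutrients, albedo in [0, 100].
#' Every record satisfies the ice-core invariants, and every temperature
#' is inside the validity domain of [brine_salinity()].
#'
#' @param seed integer seed.
#' @param n_dates number of sampling dates per site, `>= 1`.
#' @param site_labels character vector of site labels.
#' @return data frame with the same columns as [ice_core_table()].
#' @export
generate_environment_table <- function(seed = 1L, n_dates = 4L,
                                       site_labels = c("outer", "inner")) {
  if (n_dates < 1L) stop_("n_dates must be >= 1")
  with_seed(seed, {
    rows <- expand.grid(date_no = seq_len(n_dates), site = site_labels,
                        stringsAsFactors = FALSE)
    n <- nrow(rows)
    tt <- round(stats::runif(n, -10, -0.5), 1)
    data.frame(
      date = sprintf("2022-%02d-%02d", 4 + (rows$date_no - 1L) %/% 4,
                     (1 + (rows$date_no - 1L) * 9) %% 28 + 1),
      week = paste("Week", rows$date_no),
      site = rows$site,
      snow_depth_cm = round(stats::runif(n, 5, 35), 1),
      snow_depth_sd = round(stats::runif(n, 0.2, 5), 1),
      albedo_pct = round(stats::runif(n, 60, 98), 0),
      ice_thickness_cm = round(stats::runif(n, 50, 100), 0),
      ice_thickness_sd = round(stats::runif(n, 0.5, 3), 1),
      ice_temperature_c = tt,
      # bulk salinity capped below the brine salinity at the drawn
      # temperature so the implied brine state is physical (Vb < 100%)
      bulk_salinity_ppt = round(stats::runif(
        n, 2, pmin(15, 0.8 * (1000 / (1 - 54.11 / tt)))), 2),
      chl_a_ice = round(stats::rlnorm(n, 0, 0.8), 2),
      cn_ratio = round(stats::runif(n, 2.5, 12), 2),
      d13c = round(stats::runif(n, -32, -16), 2),
      d15n = round(stats::runif(n, 0.5, 5), 2),
      si_um = round(stats::rlnorm(n, 0.2, 0.9), 2),
      nox_um = round(stats::rlnorm(n, 0.8, 0.9), 2),
      po4_um = round(stats::rlnorm(n, -1, 0.5), 2),
      water_temperature_c = round(stats::runif(n, -1.9, -1.4), 2),
      stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic community count table
#'
#' Multinomial counts over a small set of sympagic taxa with a dominant
#' pennate diatom, optionally with a site-level shift in relative
#' composition; used to exercise the dissimilarity/ANOSIM stage.
#'
#' @param seed integer seed.
#' @param n_samples samples per site.
#' @param site_labels character vector of site labels.
#' @param total mean total count per sample.
#' @param shift multiplicative change in the dominant taxon's expected
#'   share between the first and the remaining sites (1 = no effect).
#' @return list with `counts` (samples x taxa integer matrix) and `site`
#'   (grouping factor).
#' @export
generate_community_table <- function(seed = 1L, n_samples = 4L,
                                     site_labels = c("outer", "inner"),
                                     total = 500L, shift = 1) {
  taxa <- c("Nitzschia_frigida", "Nitzschia_spp", "Navicula_spp",
            "Pleurosigma_Gyrosigma", "dinoflagellates", "flagellates")
  base <- c(40, 15, 15, 10, 10, 10)
  with_seed(seed, {
    site <- rep(site_labels, each = n_samples)
    counts <- t(vapply(seq_along(site), function(i) {
      p <- base
      if (site[i] != site_labels[1L]) p[1L] <- p[1L] * shift
      stats::rmultinom(1L, size = total, prob = p / sum(p))[, 1L]
    }, integer(length(taxa))))
    colnames(counts) <- taxa
    rownames(counts) <- sprintf("%s_s%d", site, rep(seq_len(n_samples),
                                                    times = length(site_labels)))
    list(counts = counts, site = factor(site, levels = site_labels))
  })
}
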