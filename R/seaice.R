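#' Silicate-amended Redfield reference ratios
#'
#' The elemental reference for diatom nutrient sufficiency,
#' C:N:Si:P = 106:16:15:1.
#'
#' @return named numeric vector `c(C = 106, N = 16, Si = 15, P = 1)`.
#' @export
redfield_reference <- function() c(C = 106, N = 16, Si = 15, P = 1)

#' Brine salinity from ice temperature
#'
#' Frankenstein-Garner relation `Sb = 1000 / (1 - 54.11 / T)` (T in degC,
#' Sb in ppt): the equilibrium salinity of the liquid brine inclusions in
#' sea ice at temperature T. Strictly decreasing in T on its domain.
#'
#' @param temperature_c ice temperature(s) in degC; must be `< 0` (no
#'   brine at or above the melting point). Values below the relation's
#'   stated validity limit (-22.9 degC) trigger a warning.
#' @return brine salinity in ppt.
#' @examples
#' brine_salinity(-2.1)  # 37.36
#' @export
brine_salinity <- function(temperature_c) {
  t <- as.numeric(temperature_c)
  if (any(!is.finite(t))) stop_("non-finite ice temperature")
  if (any(t >= 0))
    stop_("brine salinity undefined at T >= 0 degC (no brine phase); got %s",
          paste(t[t >= 0], collapse = ", "))
  if (any(t < -22.9))
    warn_("ice temperature below -22.9 degC: outside the relation's validity range")
  1000 / (1 - 54.11 / t)
}

#' Brine volume fraction of sea ice
#'
#' Default (`"density_ratio"`): `Vb/V = (S_bulk / Sb(T)) * (rho_ice /
#' rho_brine) * 100` with `rho_ice = 917 kg/m^3` and `rho_brine = 1000 +
#' 0.8 * Sb kg/m^3` -- bulk salt conservation between the solid matrix
#' and the brine inclusions, correcting for the density contrast. The
#' `"cox_weeks"` alternative uses the phase-relation polynomial
#' `Vb/V = rho_ice_gcc * S_bulk / F1(T)` with the warm-ice (T > -2 degC)
#' and cold-ice coefficient sets.
#'
#' @param bulk_salinity_ppt bulk (melted-core) salinity, `>= 0`.
#' @param temperature_c ice temperature in degC, `< 0`.
#' @param method `"density_ratio"` (default) or `"cox_weeks"`.
#' @return brine volume as % of ice volume.
#' @examples
#' brine_volume_fraction(10.80, -2.3)  # ~ 24
#' @export
brine_volume_fraction <- function(bulk_salinity_ppt, temperature_c,
                                  method = c("density_ratio", "cox_weeks")) {
  method <- match.arg(method)
  s <- as.numeric(bulk_salinity_ppt)
  if (any(!is.finite(s)) || any(s < 0)) stop_("bulk salinity must be >= 0")
  if (method == "density_ratio") {
    sb <- brine_salinity(temperature_c)
    (s / sb) * (917 / (1000 + 0.8 * sb)) * 100
  } else {
    t <- as.numeric(temperature_c)
    if (any(t >= 0)) stop_("brine volume undefined at T >= 0 degC")
    f1 <- ifelse(t >= -2,
                 -0.041221 - 18.407 * t + 0.58402 * t^2 + 0.21454 * t^3,
                 -4.732 - 22.45 * t - 0.6397 * t^2 - 0.01074 * t^3)
    100 * 0.917 * s / f1
  }
}

#' Surface albedo from incoming and reflected PAR
#'
#' @param incoming_par incoming photosynthetically active radiation
#'   (µmol photons m^-2 s^-1), `> 0`.
#' @param reflected_par reflected PAR, in `[0, incoming_par]`.
#' @return albedo in percent.
#' @export
albedo <- function(incoming_par, reflected_par) {
  if (any(incoming_par <= 0)) stop_("incoming PAR must be > 0")
  if (any(reflected_par < 0)) stop_("reflected PAR must be >= 0")
  if (any(reflected_par > incoming_par))
    stop_("reflected PAR exceeds incoming PAR")
  100 * reflected_par / incoming_par
}

#' Nutrient detection limits (µM)
#' @return named vector: `nox`, `po4`, `si`.
#' @export
nutrient_detection_limits <- function() c(nox = 0.01, po4 = 0.02, si = 0.02)

#' Nutrient stoichiometric ratios and limitation flags
#'
#' Computes molar N:Si (= NOx/Si) and Si:P (= Si/PO4) for an ice-core
#' record and flags potential limitation against the silicate-amended
#' Redfield reference (106C:16N:15Si:1P): `nitrogen_limited` when NOx
#' falls below `nitrogen_threshold_um`, `silicate_limited` when
#' N:Si > 16/15 or Si:P < 15. Concentrations below the detection limits
#' (0.01 NOx, 0.02 PO4, 0.02 Si µM) or recorded as not detected are
#' treated as missing, never as zero; a missing denominator yields a
#' missing ratio and the flags are computed from what remains.
#'
#' @param record one-row data frame (or list) with `nox_um`, `si_um`,
#'   `po4_um`; `NA` marks below-detection/not-detected values.
#' @param nitrogen_threshold_um NOx concentration regarded as potentially
#'   limiting (µM). The default 1 is deliberately conservative relative
#'   to the ~0.6 µM concentrations observed at the end of ice-algal
#'   seasons; configurable.
#' @return list: `n_si`, `si_p`, `nitrogen_limited`, `silicate_limited`
#'   (logicals, `NA` when not evaluable).
#' @export
nutrient_ratios <- function(record, nitrogen_threshold_um = 1) {
  dl <- nutrient_detection_limits()
  val <- function(x, lim) {
    x <- suppressWarnings(as.numeric(x))
    if (length(x) != 1L || is.na(x) || x < lim) NA_real_ else x
  }
  nox <- val(record$nox_um, dl[["nox"]])
  si <- val(record$si_um, dl[["si"]])
  po4 <- val(record$po4_um, dl[["po4"]])
  n_si <- if (is.na(nox) || is.na(si)) NA_real_ else nox / si
  si_p <- if (is.na(si) || is.na(po4)) NA_real_ else si / po4
  ref <- redfield_reference()
  list(
    n_si = n_si, si_p = si_p,
    nitrogen_limited = if (is.na(nox)) NA else nox < nitrogen_threshold_um,
    silicate_limited = if (is.na(n_si) && is.na(si_p)) NA else
      isTRUE(n_si > ref[["N"]] / ref[["Si"]]) || isTRUE(si_p < ref[["Si"]]))
}

#' Seasonal summary of a measurement series
#'
#' Mean, sample standard deviation (`ddof = 1`), minimum and maximum.
#' With a single value the sd is reported as `NA` by default or 0 when
#' `sd_single = 0`.
#'
#' @param values numeric vector, `n >= 1`; `NA`s are dropped.
#' @param sd_single value to report for the sd of a length-1 series
#'   (`NA_real_` by default).
#' @return named list: `mean`, `sd`, `min`, `max`, `n`.
#' @export
summarize_series <- function(values, sd_single = NA_real_) {
  v <- as.numeric(values)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop_("summarize_series needs at least one non-missing value")
  list(mean = mean(v),
       sd = if (length(v) == 1L) sd_single else stats::sd(v),
       min = min(v), max = max(v), n = length(v))
}

#' Packaged seasonal ice-core table
#'
#' One row per site x sampling date: snow and ice geometry, albedo, ice
#' temperature and bulk salinity with the derived brine state, bottom-ice
#' chlorophyll a, POC:PON, stable isotopes, macronutrients, and the
#' matching under-ice water column values. Not-detected cells are `NA`.
#'
#' @param path CSV to read; defaults to the packaged fixture.
#' @return data frame; numeric columns parsed, `N.D` -> `NA`.
#' @export
ice_core_table <- function(path = extdata_path("ice_cores.csv")) {
  tab <- utils::read.csv(path, na.strings = c("N.D", "NA", ""),
                         stringsAsFactors = FALSE)
  validate_ice_core_table(tab)
  tab
}

validate_ice_core_table <- function(tab) {
  if (any(tab$ice_temperature_c >= 0, na.rm = TRUE))
    stop_("ice temperature must be < 0 degC")
  if (any(tab$bulk_salinity_ppt < 0, na.rm = TRUE))
    stop_("bulk salinity must be >= 0")
  for (col in c("si_um", "nox_um", "po4_um"))
    if (any(tab[[col]] < 0, na.rm = TRUE)) stop_("%s must be >= 0", col)
  if (any(tab$albedo_pct < 0 | tab$albedo_pct > 100, na.rm = TRUE))
    stop_("albedo must lie in [0, 100]")
  invisible(tab)
}
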