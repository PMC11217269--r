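#' Infrared band registry for sea-ice algal biomolecules
#'
#' Nine diagnostic mid-infrared bands covering the biomolecular classes of
#' a diatom cell: unsaturated and saturated fatty-acid CH stretches
#' (3011, 2921, 2852 cm^-1), the lipid ester carbonyl (1744), protein
#' amide II (1549), carboxylated molecules (1400), phosphodiesters (1241),
#' carbohydrates (window 1146-1191, nominal centre 1168) and biogenic
#' silica (1080). Window half-widths are +-15 cm^-1 for the sharp
#' CH-stretch bands and +-25 cm^-1 in the fingerprint region, except the
#' carbohydrate window which is fixed at its conventional bounds; all are
#' configurable by editing a copy of the returned data frame.
#'
#' The registry warns when two band windows overlap by more than 25% of
#' the narrower window (the carbohydrate/silica region is the known
#' near-neighbour pair; with default widths no windows overlap).
#'
#' @param path CSV to read the registry from; defaults to the packaged
#'   registry.
#' @return data frame with columns `name`, `centre`, `window_lo`,
#'   `window_hi`, `assignment`, `biomolecule_class`, `reference`.
#' @examples
#' reg <- default_band_registry()
#' nrow(reg)            # 9 bands
#' @export
default_band_registry <- function(path = extdata_path("band_registry.csv")) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_band_registry(reg)
  reg
}

validate_band_registry <- function(reg) {
  needed <- c("name", "centre", "window_lo", "window_hi", "biomolecule_class")
  miss <- setdiff(needed, names(reg))
  if (length(miss)) stop_("registry lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(reg$name))
    stop_("duplicated band names in registry")
  bad <- !(reg$window_lo < reg$centre & reg$centre < reg$window_hi)
  if (any(bad))
    stop_("band(s) with centre outside window: %s", paste(reg$name[bad], collapse = ", "))
  if (!all(reg$biomolecule_class %in% c("storage", "functional")))
    stop_("biomolecule_class must be 'storage' or 'functional'")
  # pairwise window overlap check
  n <- nrow(reg)
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    lo <- max(reg$window_lo[i], reg$window_lo[j])
    hi <- min(reg$window_hi[i], reg$window_hi[j])
    if (hi > lo) {
      w <- min(reg$window_hi[i] - reg$window_lo[i], reg$window_hi[j] - reg$window_lo[j])
      if ((hi - lo) / w > 0.25)
        warn_("band windows '%s' and '%s' overlap by more than 25%%",
              reg$name[i], reg$name[j])
    }
  }
  invisible(reg)
}

#' Look up one band in a registry
#' @param registry a band registry data frame.
#' @param name band name.
#' @return one-row data frame.
#' @keywords internal
band_entry <- function(registry, name) {
  i <- match(name, registry$name)
  if (is.na(i)) stop_("unknown band '%s' (registry has: %s)", name,
                      paste(registry$name, collapse = ", "))
  registry[i, , drop = FALSE]
}

#' Integrate the area under one band of a preprocessed spectrum
#'
#' Trapezoidal integral over the band window of the rectified
#' second-derivative signal. In second-derivative spectroscopy an
#' absorbance peak appears as a negative lobe flanked by positive
#' side-lobes; the default rectification (`"negclip"`) zero-clips the
#' positive side-lobes and integrates the magnitude of the negative lobe,
#' which is the nonnegative choice that stays linear in the underlying
#' peak amplitude. `"abs"` integrates `|signal|` over the window instead
#' (negative and positive lobes both counted).
#'
#' Linearity in concentration (Beer-Lambert behaviour) holds at the
#' `derivative` stage; on `normalized`-stage spectra the per-spectrum SNV
#' scaling makes areas relative to the spectrum's overall signal, which is
#' what the multivariate analyses consume.
#'
#' @param s `ir_spectrum` at stage `"derivative"` or `"normalized"`.
#' @param band one-row registry entry (or a band name plus `registry`).
#' @param registry registry used when `band` is given as a name.
#' @param rectify `"negclip"` (default) or `"abs"`.
#' @return nonnegative scalar area.
#' @export
integrate_band <- function(s, band, registry = default_band_registry(),
                           rectify = c("negclip", "abs")) {
  stopifnot(inherits(s, "ir_spectrum"))
  rectify <- match.arg(rectify)
  if (s$stage == "raw")
    stop_("integrate_band expects a derivative- or normalized-stage spectrum")
  if (is.character(band)) band <- band_entry(registry, band)
  lo <- band$window_lo[1L]; hi <- band$window_hi[1L]
  o <- order(s$wavenumbers)
  wn <- s$wavenumbers[o]; y <- s$absorbance[o]
  if (lo < min(wn) || hi > max(wn))
    stop_("band '%s' window [%s, %s] outside spectrum grid [%s, %s]",
          band$name[1L], lo, hi, min(wn), max(wn))
  keep <- wn >= lo & wn <= hi
  if (sum(keep) < 2L)
    stop_("band '%s' window contains fewer than 2 samples", band$name[1L])
  integrand <- if (rectify == "negclip") pmax(-y[keep], 0) else abs(y[keep])
  trapz(wn[keep], integrand)
}

#' Per-cell biomolecular profile from its point spectra
#'
#' Aggregates the band areas of all point measurements of one cell by the
#' arithmetic mean, mirroring the practice of probing multiple apertures
#' across a cell surface and treating them as replicate measurements of
#' one individual. Zero areas map to `NA` on the log10 scale.
#'
#' @param points list of preprocessed `ir_spectrum` objects sharing one
#'   `cell_id`.
#' @param registry band registry data frame.
#' @param rectify passed to [integrate_band()].
#' @return one-row data frame: `cell_id`, `site`, `week`, `n_points`, one
#'   `area_<band>` and one `log10_<band>` column per registry band.
#' @export
profile_cell <- function(points, registry = default_band_registry(),
                         rectify = "negclip") {
  stopifnot(is.list(points), length(points) >= 1L)
  ids <- unique(vapply(points, function(p) p$cell_id, character(1)))
  if (length(ids) != 1L)
    stop_("profile_cell got mixed cell ids: %s", paste(ids, collapse = ", "))
  areas <- sapply(registry$name, function(b) {
    mean(vapply(points, integrate_band, numeric(1),
                band = b, registry = registry, rectify = rectify))
  })
  out <- data.frame(cell_id = ids, site = points[[1L]]$site,
                    week = points[[1L]]$week, n_points = length(points),
                    stringsAsFactors = FALSE)
  for (b in registry$name) {
    out[[paste0("area_", b)]] <- areas[[b]]
    out[[paste0("log10_", b)]] <- if (areas[[b]] > 0) log10(areas[[b]]) else NA_real_
  }
  out
}

#' Profile every cell in a set of point spectra
#'
#' @param spectra list of preprocessed `ir_spectrum` objects; points are
#'   grouped by `cell_id`.
#' @inheritParams profile_cell
#' @return data frame with one row per cell.
#' @export
profile_cells <- function(spectra, registry = default_band_registry(),
                          rectify = "negclip") {
  cells <- split(spectra, vapply(spectra, function(s) s$cell_id, character(1)))
  out <- do.call(rbind, lapply(cells, profile_cell,
                               registry = registry, rectify = rectify))
  rownames(out) <- NULL
  out
}

#' Shapiro-Wilk normality check with automatic log10 fallback
#'
#' Tests per-cell band areas for normality; when the raw values fail at
#' `alpha`, the test is repeated on log10 values (nonpositive values are
#' excluded, with the count reported) and the transform to use downstream
#' is flagged.
#'
#' @param values numeric vector of per-cell areas for one band, `n >= 3`.
#' @param alpha significance level (default 0.05).
#' @return list with `w_raw`, `p_raw`, `w_log`, `p_log` (NA when the log
#'   branch was not taken), `transform` (`"none"` or `"log10"`), and
#'   `n_excluded` (nonpositive values dropped before log).
#' @export
normality_check <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop_("normality check needs n >= 3 (got %d)", length(values))
  raw <- stats::shapiro.test(values)
  out <- list(w_raw = unname(raw$statistic), p_raw = raw$p.value,
              w_log = NA_real_, p_log = NA_real_,
              transform = "none", n_excluded = 0L)
  if (raw$p.value < alpha) {
    pos <- values[values > 0]
    out$n_excluded <- length(values) - length(pos)
    if (length(pos) < 3L)
      stop_("fewer than 3 positive values for the log10 branch (%d excluded)",
            out$n_excluded)
    lg <- stats::shapiro.test(log10(pos))
    out$w_log <- unname(lg$statistic)
    out$p_log <- lg$p.value
    out$transform <- "log10"
  }
  out
}

#' Saturated to unsaturated fatty-acid band ratio per cell
#'
#' (area at ~2921 + area at ~2852) / (area at ~3011). A zero unsaturated
#' band area yields `NA` with a warning rather than an infinity.
#'
#' @param profile one-row data frame from [profile_cell()].
#' @return scalar ratio (or `NA`).
#' @export
safa_usfa_ratio <- function(profile) {
  safa <- profile$area_fa_saturated_ch2_asym + profile$area_fa_saturated_ch2_sym
  usfa <- profile$area_fa_unsaturated
  if (is.na(usfa) || usfa <= 0) {
    warn_("zero unsaturated fatty-acid band area for cell %s; ratio undefined",
          profile$cell_id)
    return(NA_real_)
  }
  safa / usfa
}
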