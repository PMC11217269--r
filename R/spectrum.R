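#' Construct a single point-measurement infrared spectrum
#'
#' An `ir_spectrum` holds one absorbance measurement over a strictly
#' monotone wavenumber grid (cm^-1), together with the metadata that links
#' it to a cell, a sampling site and a sampling week, and a `stage` tag
#' that records where it sits in the preprocessing chain. The stage tag is
#' what lets downstream operations refuse out-of-order application (for
#' example, normalizing a raw spectrum before differentiating it).
#'
#' @param wavenumbers numeric vector, cm^-1, strictly monotone (either
#'   direction; acquisition order 4000 -> 800 is the convention on disk).
#' @param absorbance numeric vector, same length, all finite.
#' @param point_id,cell_id,site,week metadata labels (`NA` allowed).
#' @param stage one of `"raw"`, `"derivative"`, `"normalized"`.
#' @return an object of class `ir_spectrum`.
#' @examples
#' s <- ir_spectrum(seq(4000, 800, by = -4), rnorm(801), point_id = "p1")
#' @export
ir_spectrum <- function(wavenumbers, absorbance,
                        point_id = NA_character_, cell_id = NA_character_,
                        site = NA_character_, week = NA_character_,
                        stage = c("raw", "derivative", "normalized")) {
  stage <- match.arg(stage)
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) == 0L) stop_("empty wavenumber grid")
  if (length(wavenumbers) != length(absorbance))
    stop_("wavenumbers (%d) and absorbance (%d) differ in length",
          length(wavenumbers), length(absorbance))
  if (anyNA(wavenumbers) || any(!is.finite(wavenumbers)))
    stop_("non-finite wavenumbers")
  if (anyNA(absorbance) || any(!is.finite(absorbance)))
    stop_("non-finite absorbance values")
  d <- diff(wavenumbers)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop_("wavenumber grid is not strictly monotone")
  structure(
    list(wavenumbers = wavenumbers, absorbance = absorbance,
         point_id = as.character(point_id), cell_id = as.character(cell_id),
         site = as.character(site), week = as.character(week), stage = stage),
    class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  rng <- range(x$wavenumbers)
  cat(sprintf("<ir_spectrum> %s | %d points, %.0f-%.0f cm^-1 | stage=%s\n",
              x$point_id, length(x$wavenumbers), rng[2], rng[1], x$stage))
  invisible(x)
}

#' Grid spacing of a uniform spectrum
#'
#' Errors unless the grid spacing is constant to a 1e-6 relative
#' tolerance, as required by the derivative filter.
#'
#' @param s an `ir_spectrum`.
#' @return absolute spacing h in cm^-1.
#' @keywords internal
grid_spacing <- function(s) {
  d <- diff(s$wavenumbers)
  if (length(d) == 0L) stop_("spectrum has a single point; no spacing")
  h <- abs(mean(d))
  if (max(abs(abs(d) - h)) > 1e-6 * h)
    stop_("wavenumber grid is not uniform (required for derivative filtering)")
  h
}

#' Crop a spectrum to a wavenumber interval
#'
#' Retains samples with `lo <= wavenumber <= hi` (both ends inclusive).
#'
#' @param s an `ir_spectrum`.
#' @param lo,hi interval bounds in cm^-1, `lo < hi`.
#' @return the cropped `ir_spectrum` (stage preserved).
#' @examples
#' s <- ir_spectrum(seq(4000, 800, by = -4), rep(1, 801))
#' length(crop(s, 1100, 1770)$wavenumbers)  # 168 samples on a 4 cm^-1 grid
#' @export
crop <- function(s, lo, hi) {
  stopifnot(inherits(s, "ir_spectrum"))
  if (!(is.numeric(lo) && is.numeric(hi)) || lo >= hi)
    stop_("crop bounds must satisfy lo < hi (got lo=%s, hi=%s)", lo, hi)
  keep <- s$wavenumbers >= lo & s$wavenumbers <= hi
  if (!any(keep)) stop_("crop window [%s, %s] contains no samples", lo, hi)
  s$wavenumbers <- s$wavenumbers[keep]
  s$absorbance <- s$absorbance[keep]
  s
}

#' Crop to a union of wavenumber intervals
#'
#' Used for the analysis range (CH-stretch plus fingerprint region); the
#' retained segments are concatenated in the spectrum's own grid order.
#'
#' @param s an `ir_spectrum`.
#' @param ranges list of `c(lo, hi)` pairs.
#' @return `ir_spectrum` restricted to the union of the ranges.
#' @export
crop_ranges <- function(s, ranges) {
  stopifnot(inherits(s, "ir_spectrum"), is.list(ranges), length(ranges) >= 1L)
  keep <- rep(FALSE, length(s$wavenumbers))
  for (r in ranges) {
    if (length(r) != 2L || r[1] >= r[2])
      stop_("each range must be c(lo, hi) with lo < hi")
    keep <- keep | (s$wavenumbers >= r[1] & s$wavenumbers <= r[2])
  }
  if (!any(keep)) stop_("analysis ranges contain no samples")
  s$wavenumbers <- s$wavenumbers[keep]
  s$absorbance <- s$absorbance[keep]
  s
}

#' Write a set of spectra as wide CSV plus a metadata sidecar
#'
#' The wide CSV has the wavenumber grid in the first column (acquisition
#' order, i.e. descending from 4000 to 800 for the default grid) and one
#' column per point-spectrum, with the header row carrying the point ids.
#' The sidecar (`<path base>_metadata.csv`) maps point id to cell, site
#' and week.
#'
#' @param spectra list of `ir_spectrum` objects sharing one grid.
#' @param path output CSV path; the sidecar path is derived from it.
#' @return invisibly, the two paths written.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(is.list(spectra), length(spectra) >= 1L)
  lapply(spectra, function(s) stopifnot(inherits(s, "ir_spectrum")))
  wn <- spectra[[1L]]$wavenumbers
  for (s in spectra)
    if (!isTRUE(all.equal(s$wavenumbers, wn, tolerance = 1e-12)))
      stop_("all spectra must share one wavenumber grid to be written wide")
  ids <- vapply(spectra, function(s) s$point_id, character(1))
  if (anyDuplicated(ids)) stop_("duplicated point ids: %s",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  wide <- data.frame(wavenumber = wn, check.names = FALSE)
  for (i in seq_along(spectra)) wide[[ids[i]]] <- spectra[[i]]$absorbance
  utils::write.csv(wide, path, row.names = FALSE)
  meta <- data.frame(
    point_id = ids,
    cell_id = vapply(spectra, function(s) s$cell_id, character(1)),
    site = vapply(spectra, function(s) s$site, character(1)),
    week = vapply(spectra, function(s) s$week, character(1)))
  mpath <- metadata_path(path)
  utils::write.csv(meta, mpath, row.names = FALSE)
  invisible(c(path, mpath))
}

metadata_path <- function(path)
  paste0(sub("\\.csv$", "", path), "_metadata.csv")

#' Read spectra written by [write_spectra()]
#'
#' Parses the wide CSV, validates the grid (numeric, strictly monotone,
#' no duplicated wavenumber rows) and joins metadata from the sidecar.
#' Points missing from the sidecar are retained with `NA` metadata and a
#' warning; a missing sidecar file warns once.
#'
#' @param path path to the wide CSV.
#' @param stage stage tag to assign to the spectra read (default raw).
#' @return list of `ir_spectrum` objects.
#' @export
read_spectra <- function(path, stage = "raw") {
  if (!file.exists(path)) stop_("spectra file not found: %s", path)
  wide <- utils::read.csv(path, check.names = FALSE)
  if (ncol(wide) < 2L) stop_("wide spectra CSV needs a wavenumber column plus >= 1 spectrum")
  wn <- suppressWarnings(as.numeric(wide[[1L]]))
  if (anyNA(wn))
    stop_("non-numeric wavenumber at row(s) %s",
          paste(utils::head(which(is.na(wn)), 5L), collapse = ", "))
  if (anyDuplicated(wn))
    stop_("duplicated wavenumber rows at row(s) %s",
          paste(utils::head(which(duplicated(wn)), 5L), collapse = ", "))
  d <- diff(wn)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop_("wavenumber column is not strictly monotone")
  meta <- NULL
  mpath <- metadata_path(path)
  if (file.exists(mpath)) meta <- utils::read.csv(mpath, colClasses = "character")
  else warn_("metadata sidecar not found (%s); spectra get NA metadata", mpath)
  out <- vector("list", ncol(wide) - 1L)
  for (j in 2L:ncol(wide)) {
    y <- suppressWarnings(as.numeric(wide[[j]]))
    if (anyNA(y))
      stop_("non-numeric absorbance in column '%s' at row(s) %s",
            names(wide)[j], paste(utils::head(which(is.na(y)), 5L), collapse = ", "))
    pid <- names(wide)[j]
    m <- if (!is.null(meta)) meta[meta$point_id == pid, , drop = FALSE] else NULL
    if (!is.null(meta) && nrow(m) == 0L) {
      warn_("no metadata row for point id '%s'; retained with NA metadata", pid)
      m <- NULL
    }
    out[[j - 1L]] <- ir_spectrum(
      wn, y, point_id = pid,
      cell_id = if (!is.null(m)) m$cell_id[1L] else NA_character_,
      site = if (!is.null(m)) m$site[1L] else NA_character_,
      week = if (!is.null(m)) m$week[1L] else NA_character_,
      stage = stage)
  }
  out
}
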