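#' Savitzky-Golay convolution weights
#'
#' Least-squares weights for estimating the `deriv`-th derivative at the
#' centre of a window of `2 * half_window + 1` equally spaced samples by a
#' local polynomial of degree `polyorder`. Unit-spacing convention; callers
#' rescale by `1/h^deriv`.
#'
#' @param half_window points on either side of the centre.
#' @param polyorder local polynomial degree, `>= deriv`, `< window`.
#' @param deriv derivative order.
#' @return numeric weight vector of length `2 * half_window + 1`.
#' @keywords internal
sg_weights <- function(half_window, polyorder, deriv) {
  m <- as.integer(half_window)
  p <- as.integer(polyorder)
  if (m < 1L) stop_("half_window must be >= 1")
  if (p >= 2L * m + 1L) stop_("polyorder (%d) must be < window (%d)", p, 2L * m + 1L)
  if (deriv > p) stop_("derivative order (%d) exceeds polyorder (%d)", deriv, p)
  x <- seq.int(-m, m)
  A <- outer(x, 0:p, `^`)
  # row `deriv` of the pseudo-inverse, times deriv!
  pinv <- solve(crossprod(A), t(A))
  factorial(deriv) * pinv[deriv + 1L, ]
}

#' Savitzky-Golay smoothed second derivative of a spectrum
#'
#' Smoothing and differentiation in a single least-squares pass: a local
#' polynomial of degree `polyorder` is fitted in a sliding window of
#' `2 * half_window + 1` points and its second derivative evaluated at the
#' window centre. The result is scaled by `1/h^2` (h = grid spacing in
#' cm^-1) so values carry physical units of absorbance * cm^2; only ratios
#' matter downstream, but the scaling makes analytic cross-checks direct.
#' The `half_window` unreliable samples at each end are dropped (no
#' polynomial extrapolation).
#'
#' Because the second derivative is an even derivative, the result is
#' independent of whether the grid runs 4000 -> 800 or 800 -> 4000.
#'
#' @param s an `ir_spectrum` with `stage = "raw"` and a uniform grid.
#' @param half_window points on either side of the centre (default 4,
#'   i.e. a 9-point window).
#' @param polyorder local polynomial degree (default 3).
#' @return an `ir_spectrum` with `stage = "derivative"`, shorter by
#'   `2 * half_window` samples.
#' @examples
#' wn <- seq(4000, 800, by = -4)
#' s <- ir_spectrum(wn, wn^2)              # f(v) = v^2
#' d <- savitzky_golay_second_derivative(s)
#' range(d$absorbance)                     # all exactly 2
#' @export
savitzky_golay_second_derivative <- function(s, half_window = 4L, polyorder = 3L) {
  stopifnot(inherits(s, "ir_spectrum"))
  if (s$stage != "raw")
    stop_("savitzky_golay_second_derivative expects a raw spectrum (got stage '%s')", s$stage)
  h <- grid_spacing(s)
  m <- as.integer(half_window)
  n <- length(s$absorbance)
  if (2L * m + 1L > n)
    stop_("window (%d) exceeds spectrum length (%d)", 2L * m + 1L, n)
  w <- sg_weights(m, polyorder, deriv = 2L)
  # centred moving dot-product; interior points only
  idx <- (m + 1L):(n - m)
  d2 <- vapply(idx, function(i) sum(w * s$absorbance[(i - m):(i + m)]), numeric(1))
  s$wavenumbers <- s$wavenumbers[idx]
  s$absorbance <- d2 / h^2
  s$stage <- "derivative"
  s
}

#' Standard Normal Variate normalization
#'
#' Centres a spectrum (or plain numeric vector) to mean 0 and scales to
#' sample standard deviation 1 (`ddof = 1`). For spectra the operation is
#' applied after the derivative step, per the preprocessing order
#' raw -> derivative -> normalized, and is idempotent.
#'
#' @param x an `ir_spectrum` (stage `"derivative"` or `"normalized"`) or a
#'   numeric vector with at least 2 values.
#' @param ... unused.
#' @return object of the same kind; spectra get `stage = "normalized"`.
#' @examples
#' snv(c(1, 2, 3))  # -1 0 1
#' @export
snv <- function(x, ...) UseMethod("snv")

#' @rdname snv
#' @export
snv.default <- function(x, ...) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop_("SNV needs at least 2 values")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop_("SNV undefined for zero-variance input")
  (x - mean(x)) / s
}

#' @rdname snv
#' @export
snv.ir_spectrum <- function(x, ...) {
  if (x$stage == "raw")
    stop_("SNV is applied after the derivative step (stage 'raw' refused); see preprocess_spectrum()")
  x$absorbance <- snv.default(x$absorbance)
  x$stage <- "normalized"
  x
}

#' Default analysis ranges for SNV and band integration
#'
#' The CH-stretch region (2800-3050 cm^-1) and the fingerprint region
#' (1000-1770 cm^-1) that together contain all registry bands.
#'
#' @return list of two `c(lo, hi)` pairs.
#' @export
default_analysis_ranges <- function() list(c(2800, 3050), c(1000, 1770))

#' Run the full preprocessing chain on one spectrum
#'
#' raw -> Savitzky-Golay second derivative -> crop to the analysis
#' range(s) -> SNV over the retained samples. Set `snv_ranges = NULL` to
#' normalize over the full (derivative) acquisition range instead.
#'
#' @param s raw `ir_spectrum`.
#' @param half_window,polyorder passed to
#'   [savitzky_golay_second_derivative()].
#' @param snv_ranges list of `c(lo, hi)` analysis windows (default
#'   [default_analysis_ranges()]), or `NULL` for the full range.
#' @param normalize apply SNV (default `TRUE`); `FALSE` stops at the
#'   (cropped) derivative stage, where absolute band areas remain linear
#'   in concentration.
#' @return preprocessed `ir_spectrum`.
#' @export
preprocess_spectrum <- function(s, half_window = 4L, polyorder = 3L,
                                snv_ranges = default_analysis_ranges(),
                                normalize = TRUE) {
  d <- savitzky_golay_second_derivative(s, half_window, polyorder)
  if (!is.null(snv_ranges)) d <- crop_ranges(d, snv_ranges)
  if (normalize) d <- snv(d) else d
}
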