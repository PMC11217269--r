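#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so generators are pure
#' functions of their arguments (including the seed).
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Trapezoidal integral
#'
#' @param x ordinates (monotone increasing).
#' @param y values at `x`.
#' @return scalar integral.
#' @keywords internal
trapz <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
warn_ <- function(...) warning(sprintf(...), call. = FALSE)

#' Path to a packaged extdata fixture
#' @param file file name under `inst/extdata`.
#' @keywords internal
extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "icephenome")
  if (!nzchar(p)) stop_("packaged fixture '%s' not found", file)
  p
}
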