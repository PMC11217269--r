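#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over taxa; 0 for
#' identical samples, 1 for samples with disjoint support.
#'
#' @param counts samples x taxa matrix of nonnegative abundances; no
#'   all-zero row.
#' @return symmetric dissimilarity matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
bray_curtis <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_("negative abundances")
  zero <- rowSums(counts) == 0
  if (any(zero))
    stop_("all-zero sample(s): %s",
          paste(rownames(counts)[zero] %||% which(zero), collapse = ", "))
  n <- nrow(counts)
  D <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <-
      sum(abs(counts[i, ] - counts[j, ])) / sum(counts[i, ] + counts[j, ])
  }
  D
}

#' Clarke's ANOSIM R for one labelling
#' @param rk rank vector over the M pairwise dissimilarities.
#' @param within logical vector: pair within one group.
#' @param denom M/2.
#' @keywords internal
anosim_r <- function(rk, within, denom)
  (mean(rk[!within]) - mean(rk[within])) / denom

#' All distinct relabellings of a grouped sample
#'
#' Enumerates the distinct assignments of group labels to positions for
#' the exhaustive ANOSIM null; the count is the multinomial coefficient
#' `n! / prod(n_g!)`.
#'
#' @param counts named integer vector of group sizes.
#' @return integer matrix, one relabelling per column (label indices).
#' @keywords internal
enumerate_labelings <- function(counts) {
  n <- sum(counts)
  rec <- function(pos, counts) {
    g <- which(counts > 0)[1L]
    if (length(pos) == counts[g] && sum(counts > 0) == 1L) {
      lab <- integer(n); lab[pos] <- g
      return(matrix(lab, ncol = 1L))
    }
    sub <- utils::combn(pos, counts[g])
    cols <- lapply(seq_len(ncol(sub)), function(k) {
      rest <- counts; rest[g] <- 0L
      tails <- rec(setdiff(pos, sub[, k]), rest)
      tails[sub[, k], ] <- g
      tails
    })
    do.call(cbind, cols)
  }
  rec(seq_len(n), as.integer(counts))
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's rank-based test of group separation on a dissimilarity
#' matrix: `R = (mean rank between - mean rank within) / (M/2)` with
#' `M = n(n-1)/2` pairwise dissimilarities ranked with average ties.
#' `R ~ 0` means groups are indistinguishable, 1 means all between-group
#' dissimilarities exceed all within-group ones. Significance by
#' permuting group labels; the exact null (all distinct relabellings) is
#' enumerated automatically when there are at most
#' `exhaustive_limit` of them, otherwise `n_permutations` random
#' relabellings are drawn and the add-one estimate
#' `p = (1 + #(R* >= R)) / (n_permutations + 1)` reported.
#'
#' @param d dissimilarity matrix (or `dist`).
#' @param groups group labels, `>= 2` groups with `>= 2` members each.
#' @param n_permutations random permutations (default 999).
#' @param seed integer seed for the permutation draw.
#' @param exhaustive_limit enumerate the exact null when the number of
#'   distinct relabellings is at most this (default 10000).
#' @return object of class `anosim_result`: `statistic`, `p_value`,
#'   `n_permutations` (or the enumeration size), `method`
#'   (`"exhaustive"` or `"sampled"`), `seed`, `metric`.
#' @export
anosim <- function(d, groups, n_permutations = 999L, seed = 1L,
                   exhaustive_limit = 10000L) {
  D <- as.matrix(d)
  n <- nrow(D)
  groups <- as.factor(groups)
  if (length(groups) != n) stop_("groups length (%d) != samples (%d)",
                                 length(groups), n)
  sizes <- table(groups)
  if (length(sizes) < 2L) stop_("ANOSIM needs >= 2 groups")
  if (any(sizes < 2L))
    stop_("group(s) with a single member: %s",
          paste(names(sizes)[sizes < 2L], collapse = ", "))
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  rk <- rank(D[upper.tri(D)])
  denom <- (n * (n - 1) / 2) / 2
  gi <- as.integer(groups)
  within_of <- function(lab) lab[pairs[, 1L]] == lab[pairs[, 2L]]
  r_obs <- anosim_r(rk, within_of(gi), denom)
  n_distinct <- factorial(n) / prod(factorial(as.integer(sizes)))
  if (is.finite(n_distinct) && n_distinct <= exhaustive_limit) {
    labs <- enumerate_labelings(stats::setNames(as.integer(sizes), names(sizes)))
    r_all <- apply(labs, 2L, function(lab) anosim_r(rk, within_of(lab), denom))
    p <- sum(r_all >= r_obs - 1e-12) / length(r_all)
    method <- "exhaustive"
    nperm <- length(r_all)
  } else {
    r_perm <- with_seed(seed, vapply(seq_len(n_permutations), function(k) {
      anosim_r(rk, within_of(sample(gi)), denom)
    }, numeric(1)))
    p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (n_permutations + 1)
    method <- "sampled"
    nperm <- n_permutations
  }
  structure(list(statistic = r_obs, p_value = p, n_permutations = nperm,
                 method = method, seed = seed, metric = "supplied"),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM R = %.4f, p = %.4g (%s null, %d relabellings, seed %s)\n",
              x$statistic, x$p_value, x$method, x$n_permutations, x$seed))
  invisible(x)
}

#' Principal component analysis
#'
#' Centred (and by default unit-variance-scaled) PCA by singular value
#' decomposition. Axes are ordered by decreasing explained variance;
#' loadings are orthonormal; scores reproduce the centred/scaled data
#' when multiplied against the loadings.
#'
#' @param x samples x variables numeric matrix, no missing values.
#' @param centre,scale centre/scale columns (defaults `TRUE`).
#' @return object of class `ordination_result`: `scores`, `loadings`,
#'   `explained` (variance fractions), `eigenvalues`.
#' @export
pca_ordination <- function(x, centre = TRUE, scale = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L) stop_("PCA needs >= 2 samples and >= 2 variables")
  if (anyNA(x)) stop_("PCA input contains missing values")
  if (scale) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0))
      stop_("constant column(s) cannot be scaled: %s",
            paste(colnames(x)[sds == 0] %||% which(sds == 0), collapse = ", "))
  }
  z <- scale(x, center = centre, scale = scale)
  sv <- svd(z)
  eig <- sv$d^2 / (nrow(x) - 1L)
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_along(sv$d)))
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_along(sv$d)))
  structure(list(scores = scores, loadings = loadings,
                 explained = eig / sum(eig), eigenvalues = eig,
                 kind = "pca"),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<%s ordination> %d axes; explained: %s\n", x$kind,
              length(x$explained),
              paste(sprintf("%.1f%%", 100 * utils::head(x$explained, 4L)),
                    collapse = ", ")))
  if (!is.null(x$p_value))
    cat(sprintf("  constrained fraction %.3f, pseudo-F %.3f, p = %.4g (%d permutations, seed %s)\n",
                x$constrained_fraction, x$pseudo_f, x$p_value,
                x$n_permutations, x$seed))
  invisible(x)
}

rda_fit <- function(yc, xc) {
  q <- qr(xc)
  if (q$rank < ncol(xc)) {
    drop <- colnames(xc)[q$pivot[(q$rank + 1L):ncol(xc)]] %||%
      q$pivot[(q$rank + 1L):ncol(xc)]
    stop_("predictor matrix is rank deficient; collinear column(s): %s",
          paste(drop, collapse = ", "))
  }
  qr.fitted(q, yc)
}

# pseudo-F from fitted/residual sums of squares; an exact fit gives Inf
rda_pseudo_f <- function(yc, xc) {
  yhat <- rda_fit(yc, xc)
  ss_fit <- sum(yhat^2)
  ss_res <- sum((yc - yhat)^2)
  qdf <- ncol(xc)
  n <- nrow(yc)
  if (ss_res <= 1e-12 * ss_fit) return(list(f = Inf, r2 = 1, ss_fit = ss_fit))
  list(f = (ss_fit / qdf) / (ss_res / (n - 1L - qdf)),
       r2 = ss_fit / (ss_fit + ss_res), ss_fit = ss_fit)
}

#' Redundancy analysis with a Monte-Carlo permutation test
#'
#' Constrains a (centred, optionally scaled) response matrix to the
#' column space of a predictor matrix by multivariate least squares.
#' The constrained variance fraction is the trace R-squared,
#' `sum(Yhat^2) / sum(Yc^2)`; constrained axes come from the singular
#' value decomposition of the fitted values. Significance of the
#' overall constraint is assessed with a pseudo-F statistic
#' `(SS_fit / q) / (SS_res / (n - 1 - q))` under row permutation of the
#' predictors, with the add-one p convention.
#'
#' @param y response matrix (samples x variables).
#' @param x predictor matrix (samples x predictors), full column rank.
#' @param n_permutations Monte-Carlo permutations (default 999).
#' @param seed integer seed.
#' @param scale_y scale response columns to unit variance (default
#'   `TRUE`, appropriate for bands of heterogeneous magnitude).
#' @return `ordination_result` with `scores`, `loadings`, `explained`
#'   (fractions of *total* variance per constrained axis),
#'   `constrained_fraction`, `pseudo_f`, `p_value`, `n_permutations`,
#'   `seed`.
#' @export
rda_ordination <- function(y, x, n_permutations = 999L, seed = 1L,
                           scale_y = TRUE) {
  y <- as.matrix(y); x <- as.matrix(x)
  if (nrow(y) != nrow(x)) stop_("response and predictors differ in row count")
  n <- nrow(y)
  yc <- scale(y, center = TRUE, scale = scale_y)
  if (scale_y && anyNA(yc)) stop_("constant response column cannot be scaled")
  xc <- scale(x, center = TRUE, scale = FALSE)
  yhat <- rda_fit(yc, xc)
  ss_tot <- sum(yc^2)
  ss_fit <- sum(yhat^2)
  obs <- rda_pseudo_f(yc, xc)
  fstat <- obs$f
  f_perm <- with_seed(seed, vapply(seq_len(n_permutations), function(k) {
    rda_pseudo_f(yc, xc[sample(n), , drop = FALSE])$f
  }, numeric(1)))
  p <- (1 + sum(f_perm >= fstat * (1 - 1e-12))) / (n_permutations + 1)
  sv <- svd(yhat)
  nax <- sum(sv$d > 1e-10 * max(sv$d, 1))
  scores <- sv$u[, seq_len(nax), drop = FALSE] %*%
    diag(sv$d[seq_len(nax)], nax)
  dimnames(scores) <- list(rownames(y), paste0("RDA", seq_len(nax)))
  loadings <- sv$v[, seq_len(nax), drop = FALSE]
  dimnames(loadings) <- list(colnames(y), paste0("RDA", seq_len(nax)))
  structure(list(scores = scores, loadings = loadings,
                 explained = (sv$d^2 / ss_tot)[seq_len(nax)],
                 eigenvalues = sv$d[seq_len(nax)]^2 / (n - 1L),
                 constrained_fraction = ss_fit / ss_tot,
                 pseudo_f = fstat, p_value = p,
                 n_permutations = n_permutations, seed = seed,
                 kind = "rda"),
            class = "ordination_result")
}

#' Forward model optimisation for redundancy analysis
#'
#' Greedy forward selection: at each step the candidate predictor adding
#' the most constrained variance is tested with a partial pseudo-F under
#' permutation of that candidate's rows, and retained when its add-one p
#' falls below `alpha`. Mirrors the practice of displaying only
#' significant constraint vectors.
#'
#' @inheritParams rda_ordination
#' @param alpha retention threshold (default 0.05).
#' @return list: `selected` (predictor names, possibly empty),
#'   `trace` (data frame of tested steps), and `model` (the
#'   [rda_ordination()] fit on the selected predictors, or `NULL`).
#' @export
rda_forward_select <- function(y, x, alpha = 0.05, n_permutations = 999L,
                               seed = 1L, scale_y = TRUE) {
  y <- as.matrix(y); x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(y)
  yc <- scale(y, center = TRUE, scale = scale_y)
  ss_tot <- sum(yc^2)
  r2_of <- function(cols, xmat) {
    if (length(cols) == 0L) return(0)
    sum(rda_fit(yc, scale(xmat[, cols, drop = FALSE], TRUE, FALSE))^2) / ss_tot
  }
  selected <- character(0)
  remaining <- colnames(x)
  trace <- list()
  step <- 0L
  while (length(remaining)) {
    step <- step + 1L
    r2_base <- r2_of(selected, x)
    gains <- vapply(remaining, function(j) r2_of(c(selected, j), x) - r2_base,
                    numeric(1))
    cand <- remaining[which.max(gains)]
    k <- length(selected) + 1L
    pf <- function(r2f) ((r2f - r2_base) / 1) / ((1 - r2f) / (n - 1L - k))
    f_obs <- pf(r2_of(c(selected, cand), x))
    f_perm <- with_seed(seed + step, vapply(seq_len(n_permutations), function(b) {
      xp <- x
      xp[, cand] <- xp[sample(n), cand]
      pf(r2_of(c(selected, cand), xp))
    }, numeric(1)))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (n_permutations + 1)
    trace[[step]] <- data.frame(step = step, candidate = cand,
                                added_r2 = gains[[cand]], partial_f = f_obs,
                                p_value = p, retained = p < alpha)
    if (p >= alpha) break
    selected <- c(selected, cand)
    remaining <- setdiff(remaining, cand)
  }
  model <- if (length(selected))
    rda_ordination(y, x[, selected, drop = FALSE],
                   n_permutations = n_permutations, seed = seed,
                   scale_y = scale_y)
  else NULL
  list(selected = selected, trace = do.call(rbind, trace), model = model)
}

#' Ordinary least-squares regression with F and R-squared reporting
#'
#' Simple univariate OLS with the conventional reporting triple
#' `(F_(1, n-2), p, R^2)`; `F = (R^2 / (1 - R^2)) * (n - 2)`, reported as
#' `Inf` for an exact fit. A residual-vs-fitted diagnostic (Pearson
#' correlation of |residual| with fitted values) is included as a cheap
#' homoscedasticity screen.
#'
#' @param x predictor, `n >= 3`, nonconstant.
#' @param y response, same length.
#' @return object of class `regression_result`: `slope`, `intercept`,
#'   `f_statistic`, `df`, `r_squared`, `p_value`,
#'   `residual_fitted_cor`, `n`.
#' @export
linear_regression <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_("regression needs n >= 3 (got %d)", n)
  if (stats::var(x) == 0) stop_("constant predictor")
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  resid <- y - fitted
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  f <- if (r2 >= 1 - 1e-15) Inf else (r2 / (1 - r2)) * (n - 2L)
  p <- if (is.infinite(f)) 0 else stats::pf(f, 1, n - 2L, lower.tail = FALSE)
  rfcor <- if (stats::sd(abs(resid)) == 0 || stats::sd(fitted) == 0) NA_real_
  else stats::cor(abs(resid), fitted)
  structure(list(slope = slope, intercept = intercept, f_statistic = f,
                 df = c(1L, n - 2L), r_squared = r2, p_value = p,
                 residual_fitted_cor = rfcor, n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: y = %.4g + %.4g x | F_%d,%d = %.4g, p = %.3g, R^2 = %.3f\n",
              x$intercept, x$slope, x$df[1], x$df[2], x$f_statistic,
              x$p_value, x$r_squared))
  invisible(x)
}
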