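test_that("Bray-Curtis dissimilarity has the hand-computed values and bounds", {
  expect_equal(bray_curtis(rbind(c(1, 1, 0), c(0, 1, 1)))[1, 2], 0.5)
  expect_equal(bray_curtis(rbind(c(2, 3), c(2, 3)))[1, 2], 0)
  expect_equal(bray_curtis(rbind(c(5, 0), c(0, 7)))[1, 2], 1)
  X <- icephenome:::with_seed(1L, matrix(rexp(24), 6, 4))
  D <- bray_curtis(X)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0) && all(D >= 0 & D <= 1))
  expect_error(bray_curtis(rbind(c(1, 2), c(0, 0))), "all-zero")
  expect_error(bray_curtis(rbind(c(1, -2), c(1, 1))), "negative")
})

test_that("Bray-Curtis and ANOSIM R agree with the vegan oracle", {
  skip_if_not_installed("vegan")
  X <- icephenome:::with_seed(42L, matrix(rexp(8 * 5), 8, 5))
  D <- bray_curtis(X)
  expect_equal(max(abs(D - as.matrix(vegan::vegdist(X)))), 0, tolerance = 1e-12)
  g <- rep(c("a", "b"), each = 4)
  expect_equal(anosim(D, g)$statistic,
               unname(vegan::anosim(as.dist(D), g, permutations = 0)$statistic),
               tolerance = 1e-12)
})

test_that("ANOSIM reaches R = 1 for fully separated groups", {
  # all between-group dissimilarities exceed all within-group ones
  X <- rbind(matrix(c(1, 0, 1.1, 0, 0.9, 0.05), 3, 2, byrow = TRUE),
             matrix(c(0, 10, 0.1, 10.5, 0.05, 9.7), 3, 2, byrow = TRUE))
  res <- anosim(as.matrix(dist(X)), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 1)
  expect_identical(res$method, "exhaustive")  # 20 relabellings enumerated
  expect_equal(res$p_value, 2 / 20)           # both complementary splits tie
})

test_that("sampled ANOSIM p agrees with exhaustive enumeration within MC error", {
  X <- icephenome:::with_seed(7L, {
    x <- matrix(rlnorm(6 * 5), 6, 5); x[4:6, ] <- x[4:6, ] * 1.6; x
  })
  D <- bray_curtis(X)
  g <- rep(c("a", "b"), each = 3)
  ex <- anosim(D, g)
  sa <- anosim(D, g, n_permutations = 999, seed = 11, exhaustive_limit = 1)
  expect_identical(ex$method, "exhaustive")
  expect_identical(sa$method, "sampled")
  expect_lt(abs(ex$p_value - sa$p_value), 0.02)
  # seed determinism of the sampled path
  expect_identical(sa$p_value,
                   anosim(D, g, n_permutations = 999, seed = 11,
                          exhaustive_limit = 1)$p_value)
})

test_that("ANOSIM is calibrated under the null (seeded simulation)", {
  # identically drawn groups: expect |R| < 0.1 and p > 0.05; per-repeat
  # success probability is 0.95 by construction, so the bound is the
  # binomial 99% lower bound for 100 repeats, not 95 itself
  res <- vapply(1:100, function(s) {
    X <- icephenome:::with_seed(s, matrix(rlnorm(26 * 6), 26, 6))
    a <- anosim(bray_curtis(X), rep(c("a", "b"), each = 13),
                n_permutations = 199, seed = s)
    c(a$statistic, a$p_value)
  }, numeric(2))
  expect_gte(sum(abs(res[1, ]) < 0.1 & res[2, ] > 0.05), 88L)
})

test_that("ANOSIM rejects degenerate groupings", {
  D <- as.matrix(dist(matrix(rnorm(10), 5, 2)))
  expect_error(anosim(D, c("a", "a", "a", "a", "b")), "single member")
  expect_error(anosim(D, rep("a", 5)), ">= 2 groups")
})

test_that("PCA matches an independent eigen-decomposition oracle", {
  X <- icephenome:::with_seed(3L, matrix(rnorm(40 * 6), 40, 6))
  ord <- pca_ordination(X)
  eig <- eigen(cov(scale(X)), symmetric = TRUE)$values
  expect_equal(ord$explained, eig / sum(eig), tolerance = 1e-10)
  # loadings orthonormal; scores reconstruct the scaled data
  expect_equal(crossprod(ord$loadings), diag(6), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(ord$scores %*% t(ord$loadings), scale(X), tolerance = 1e-8,
               ignore_attr = TRUE)
  # axes ordered by decreasing variance
  expect_true(all(diff(ord$explained) <= 1e-12))
})

test_that("PCA invariances and degenerate inputs", {
  x <- icephenome:::with_seed(8L, rnorm(30))
  XY <- cbind(x, y = 3 * x)
  expect_equal(pca_ordination(XY)$explained[1], 1)        # collinear data
  X <- icephenome:::with_seed(9L, matrix(rnorm(25 * 4), 25, 4))
  Q <- qr.Q(qr(icephenome:::with_seed(10L, matrix(rnorm(16), 4, 4))))
  expect_equal(pca_ordination(X %*% Q, scale = FALSE)$explained,
               pca_ordination(X, scale = FALSE)$explained, tolerance = 1e-9)
  Xc <- X; Xc[, 2] <- 5
  colnames(Xc) <- paste0("v", 1:4)
  expect_error(pca_ordination(Xc), "v2")
  expect_error(pca_ordination(X[1, , drop = FALSE]), ">= 2 samples")
})

test_that("RDA constrained fraction equals the least-squares trace oracle", {
  Y <- icephenome:::with_seed(21L, matrix(rnorm(30 * 4), 30, 4))
  X <- icephenome:::with_seed(22L, matrix(rnorm(30 * 3), 30, 3))
  res <- rda_ordination(Y, X, n_permutations = 99, seed = 1, scale_y = FALSE)
  Yc <- scale(Y, scale = FALSE)
  fit <- lm.fit(cbind(1, X), Y)
  yhat_c <- scale(Y - fit$residuals, scale = FALSE)
  expect_equal(res$constrained_fraction, sum(yhat_c^2) / sum(Yc^2),
               tolerance = 1e-10)
  skip_if_not_installed("vegan")
  v <- vegan::rda(Y ~ X)
  expect_equal(res$constrained_fraction, unname(v$CCA$tot.chi / v$tot.chi),
               tolerance = 1e-10)
})

test_that("RDA recognises exact linear structure and rank deficiency", {
  X <- icephenome:::with_seed(23L, matrix(rnorm(20 * 2), 20, 2))
  B <- matrix(c(1, 2, -1, 0.5, 0.3, -2), 2, 3)
  res <- rda_ordination(X %*% B, X, n_permutations = 99, seed = 5,
                        scale_y = FALSE)
  expect_equal(res$constrained_fraction, 1, tolerance = 1e-10)
  expect_equal(res$p_value, 1 / 100)          # smallest attainable
  Xr <- cbind(a = X[, 1], b = X[, 2], c = X[, 1] + X[, 2])
  expect_error(rda_ordination(X %*% B, Xr, n_permutations = 9), "c")
  expect_error(rda_ordination(matrix(1, 3, 2), matrix(rnorm(8), 4, 2)),
               "row count")
})

test_that("RDA variance fractions are invariant to sample reordering", {
  Y <- icephenome:::with_seed(31L, matrix(rnorm(24 * 3), 24, 3))
  X <- icephenome:::with_seed(32L, matrix(rnorm(24 * 2), 24, 2))
  perm <- icephenome:::with_seed(33L, sample(24))
  a <- rda_ordination(Y, X, n_permutations = 9, seed = 1)
  b <- rda_ordination(Y[perm, ], X[perm, ], n_permutations = 9, seed = 1)
  expect_equal(a$constrained_fraction, b$constrained_fraction, tolerance = 1e-10)
  expect_equal(a$explained, b$explained, tolerance = 1e-10)
})

test_that("forward selection keeps true predictors and drops pure noise", {
  n <- 40L
  X <- icephenome:::with_seed(41L, cbind(signal1 = rnorm(n), signal2 = rnorm(n),
                                         noise1 = rnorm(n), noise2 = rnorm(n)))
  Y <- icephenome:::with_seed(42L,
    cbind(X[, 1] + 0.5 * X[, 2] + rnorm(n, sd = 0.3),
          0.8 * X[, 1] - X[, 2] + rnorm(n, sd = 0.3)))
  sel <- rda_forward_select(Y, X, n_permutations = 199, seed = 2)
  expect_setequal(sel$selected, c("signal1", "signal2"))
  expect_s3_class(sel$model, "ordination_result")
  expect_true(all(sel$trace$p_value[sel$trace$retained] < 0.05))
})

test_that("linear regression reports the conventional F / R-squared triple", {
  x <- 1:10
  r <- linear_regression(x, 2 * x)
  expect_equal(r$r_squared, 1)
  expect_identical(r$f_statistic, Inf)   # overflow-safe sentinel
  expect_equal(r$p_value, 0)
  expect_equal(r$slope, 2)
  r2 <- linear_regression(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
  fit <- lm(c(1.1, 1.9, 3.2, 3.8) ~ c(1, 2, 3, 4))
  expect_equal(r2$f_statistic, summary(fit)$fstatistic[["value"]],
               tolerance = 1e-10)
  expect_equal(r2$r_squared, summary(fit)$r.squared, tolerance = 1e-12)
  expect_error(linear_regression(c(1, 2), c(1, 2)), "n >= 3")
  expect_error(linear_regression(rep(1, 5), rnorm(5)), "constant")
})

test_that("regression recovers a known slope within its standard error", {
  ok <- sum(vapply(1:100, function(s) {
    d <- icephenome:::with_seed(s, {
      x <- rnorm(40); list(x = x, y = 1.5 * x + rnorm(40, sd = 0.8))
    })
    fit <- lm(d$y ~ d$x)
    se <- summary(fit)$coefficients[2, 2]
    abs(linear_regression(d$x, d$y)$slope - 1.5) <= 2 * se
  }, logical(1)))
  expect_gte(ok, 93L)
})
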