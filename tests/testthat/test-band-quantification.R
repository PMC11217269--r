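test_that("the default registry matches the published band table", {
  reg <- default_band_registry()
  expect_equal(nrow(reg), 9L)
  expect_setequal(reg$centre, c(3011, 2921, 2852, 1744, 1549, 1400, 1241, 1168, 1080))
  carb <- reg[reg$name == "carbohydrate", ]
  expect_equal(c(carb$window_lo, carb$window_hi), c(1146, 1191))
  expect_true(all(reg$window_lo < reg$centre & reg$centre < reg$window_hi))
  expect_true(all(reg$biomolecule_class %in% c("storage", "functional")))
})

test_that("registry validation flags window overlap above 25%", {
  reg <- default_band_registry()
  reg$window_hi[reg$name == "carbohydrate"] <- 1100  # invades silica window
  reg$centre[reg$name == "carbohydrate"] <- 1090
  reg$window_lo[reg$name == "carbohydrate"] <- 1060
  expect_warning(validate_band_registry <- icephenome:::validate_band_registry(reg),
                 "overlap")
})

test_that("band integration is zero on silence and linear in amplitude", {
  wn <- seq(4000, 800, by = -4)
  flat <- ir_spectrum(wn, rep(0, length(wn)), stage = "derivative")
  expect_equal(integrate_band(flat, "silica", the_registry), 0)
  a1 <- derivative_area("lipid_ester_carbonyl", 0.5)
  a2 <- derivative_area("lipid_ester_carbonyl", 1.0)
  expect_equal(a2 / a1, 2, tolerance = 0.001)
  # linearity through the origin over 11 amplitudes
  amps <- seq(0.1, 1.1, by = 0.1)
  areas <- vapply(amps, function(a) derivative_area("protein_amide_ii", a),
                  numeric(1))
  fit <- lm(areas ~ amps)
  expect_gt(cor(areas, amps)^2, 0.999)
  expect_lt(abs(coef(fit)[[1]]) / coef(fit)[[2]], 1e-6)
})

test_that("integration agrees with a brute-force local-polynomial oracle", {
  # oracle: per-point least-squares cubic over the 9-sample window (lm),
  # second derivative from its coefficients, trapezoid over the band window
  band <- "fa_saturated_ch2_asym"
  e <- the_registry[the_registry$name == band, ]
  s <- single_band_spectrum(band, amount = 1)
  o <- order(s$wavenumbers)
  wn <- s$wavenumbers[o]; y <- s$absorbance[o]
  h <- 4
  d2 <- rep(NA_real_, length(wn))
  for (i in 5:(length(wn) - 4)) {
    u <- (wn[(i - 4):(i + 4)] - wn[i])
    fit <- lm(y[(i - 4):(i + 4)] ~ u + I(u^2) + I(u^3))
    d2[i] <- 2 * coef(fit)[[3]]
  }
  keep <- wn >= e$window_lo & wn <= e$window_hi
  oracle <- sum(diff(wn[keep]) * (pmax(-d2[keep], 0)[-1] +
                                    pmax(-d2[keep], 0)[-sum(keep)]) / 2)
  got <- integrate_band(preprocess_spectrum(s, normalize = FALSE), band,
                        the_registry)
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("integration converges to the analytic |second derivative| for wide bands", {
  # with sigma (80 cm^-1) much wider than the 9-point window, filter bias
  # is negligible; the |signal| kinks at the zero crossings still carry an
  # O(h^2) trapezoid error, so abs mode gets twice the slack
  reg <- data.frame(name = "wide", centre = 2500, window_lo = 2380,
                    window_hi = 2620, assignment = "synthetic wide band",
                    biomolecule_class = "storage", reference = "synthetic")
  s <- generate_cell_spectrum(
    data.frame(band_name = "wide", amount = 1, peak_sigma = 80),
    baseline_coefficients = 0, noise_sd = 0, registry = reg)
  d <- savitzky_golay_second_derivative(s)
  for (mode in c("abs", "negclip")) {
    x <- seq(2380, 2620, length.out = 40001)
    g2 <- gaussian_d2(x, 2500, 80)
    integrand <- if (mode == "abs") abs(g2) else pmax(-g2, 0)
    oracle <- sum((integrand[-1] + integrand[-length(x)]) / 2) * diff(x)[1]
    expect_equal(integrate_band(d, reg[1, ], rectify = mode), oracle,
                 tolerance = if (mode == "abs") 0.02 else 0.01)
  }
})

test_that("integration errors when the window leaves the grid", {
  s <- single_band_spectrum("silica")
  d <- preprocess_spectrum(s, snv_ranges = list(c(1000, 1100)),
                           normalize = FALSE)
  expect_error(integrate_band(d, "protein_amide_ii", the_registry), "outside")
  expect_error(integrate_band(single_band_spectrum("silica"), "silica",
                              the_registry), "derivative- or normalized")
})

test_that("injecting one band leaves the others silent (cross-talk < 2%)", {
  s <- single_band_spectrum("protein_amide_ii", amount = 1)
  d <- preprocess_spectrum(s, normalize = FALSE)
  own <- integrate_band(d, "protein_amide_ii", the_registry)
  for (b in setdiff(the_registry$name, "protein_amide_ii"))
    expect_lt(integrate_band(d, b, the_registry) / own, 0.02)
})

test_that("areas ignore constant and linear baselines", {
  base <- derivative_area("carbohydrate", 0.6)
  with_base <- {
    s <- single_band_spectrum("carbohydrate", 0.6, baseline = c(5, 2))
    integrate_band(preprocess_spectrum(s, normalize = FALSE), "carbohydrate",
                   the_registry)
  }
  expect_equal(with_base, base, tolerance = 1e-9)
})

test_that("profile_cell aggregates points by the mean and guards cell identity", {
  d <- two_group_design(n_cells = 1L, points_per_cell = 3L)
  pre <- lapply(generate_cohort(d)$spectra, preprocess_spectrum,
                normalize = FALSE)
  one <- profile_cell(pre[1], the_registry)     # single point: identity
  two <- profile_cell(pre[c(1, 1)], the_registry)
  expect_equal(two$area_silica, one$area_silica)
  expect_equal(one$n_points, 1L)
  mixed <- pre[1:3]
  mixed[[2]]$cell_id <- "other"
  expect_error(profile_cell(mixed, the_registry), "mixed cell ids")
  # mean of areas {a, 3a} is 2a
  s1 <- preprocess_spectrum(single_band_spectrum("silica", 1), normalize = FALSE)
  s3 <- preprocess_spectrum(single_band_spectrum("silica", 3), normalize = FALSE)
  p <- profile_cell(list(s1, s3), the_registry)
  expect_equal(p$area_silica,
               2 * integrate_band(s1, "silica", the_registry),
               tolerance = 1e-9)
  expect_equal(p$log10_silica, log10(p$area_silica))
})

test_that("normality check flags log-normal data and passes normal data", {
  # seeded simulation at n = 50: raw rejected, log10 accepted, jointly >= 90/100
  ok <- sum(vapply(1:100, function(s) {
    v <- icephenome:::with_seed(s, rlnorm(50))
    r <- normality_check(v)
    r$transform == "log10" && r$p_log > 0.05
  }, logical(1)))
  expect_gte(ok, 90L)
  # analytic standard-normal quantile sample is as normal as data can be
  r <- normality_check(qnorm(ppoints(50)))
  expect_identical(r$transform, "none")
  expect_gt(r$p_raw, 0.05)
  expect_error(normality_check(c(1, 2)), "n >= 3")
})

test_that("SAFA:USFA ratio combines the CH-stretch bands", {
  prof <- data.frame(cell_id = "c1", area_fa_saturated_ch2_asym = 2,
                     area_fa_saturated_ch2_sym = 1, area_fa_unsaturated = 1)
  expect_equal(safa_usfa_ratio(prof), 3)
  prof2 <- data.frame(cell_id = "c1", area_fa_saturated_ch2_asym = 0.4,
                      area_fa_saturated_ch2_sym = 0.4, area_fa_unsaturated = 0.4)
  expect_equal(safa_usfa_ratio(prof2), 2)
  prof$area_fa_unsaturated <- 0
  expect_warning(r <- safa_usfa_ratio(prof), "undefined")
  expect_true(is.na(r))
})

test_that("an injected SAFA:USFA ratio of 4 is recovered within 5%", {
  comp <- default_cell_composition()
  comp["fa_saturated_ch2_asym"] <- 0.4
  comp["fa_saturated_ch2_sym"] <- 0.4
  comp["fa_unsaturated"] <- 0.2
  d <- cohort_design(groups = list(list(site = "s", week = "w", n_cells = 26L,
                                        composition = comp, cv = 0.1)),
                     points_per_cell = 1L, seed = 9L)
  pre <- lapply(generate_cohort(d)$spectra, preprocess_spectrum,
                normalize = FALSE)
  prof <- profile_cells(pre, the_registry)
  ratios <- vapply(seq_len(nrow(prof)),
                   function(i) safa_usfa_ratio(prof[i, ]), numeric(1))
  expect_equal(mean(ratios), 4, tolerance = 0.05)
})
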