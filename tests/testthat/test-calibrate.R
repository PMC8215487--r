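test_that("reference-curve fitting recovers exact log-linear data", {
  crv <- generate_reference_curve("X", c(1, 10, 100, 1000), slope = 0.9,
                                  intercept = -2, noise_sd = 0)
  fit <- fit_reference_curve(crv)
  expect_equal(fit$slope, 0.9, tolerance = 1e-12)
  expect_equal(fit$intercept, -2, tolerance = 1e-12)
  expect_equal(fit$adj_r2, 1.0, tolerance = 1e-12)
  expect_equal(fit$amount_range, c(1, 1000))
})

test_that("flat curves yield zero slope and non-positive adjusted R2", {
  crv <- data.frame(amount_pg = rep(c(1, 10, 100), each = 3),
                    intensity = 5)
  fit <- fit_reference_curve(crv)
  expect_equal(fit$slope, 0)
  expect_lte(fit$adj_r2, 0)
})

test_that("sub-threshold replicates are dropped, degenerate curves rejected", {
  crv <- data.frame(amount_pg = c(1, 1, 10, 10), intensity = c(0, 2, 0, 20))
  expect_warning(fit <- fit_reference_curve(crv), "non-positive")
  expect_equal(fit$n_points, 2)
  expect_error(
    suppressWarnings(fit_reference_curve(
      data.frame(amount_pg = c(1, 10), intensity = c(2, 0)))),
    "distinct")
  expect_error(
    suppressWarnings(fit_reference_curve(
      data.frame(amount_pg = c(1, 10), intensity = c(0, 0)))),
    "non-positive")
})

test_that("inverse prediction inverts the calibration and flags extrapolation", {
  crv <- generate_reference_curve("X", c(1, 10, 100, 1000), slope = 0.9,
                                  intercept = -2, noise_sd = 0)
  fit <- fit_reference_curve(crv)
  pred <- predict_amount(fit, 10^0.7)
  expect_equal(pred$amount_pg, 1000, tolerance = 1e-9)
  expect_equal(pred$status, "in_range")

  # identity curve
  idfit <- fit_reference_curve(
    data.frame(amount_pg = c(1, 10, 100), intensity = c(1, 10, 100)))
  expect_equal(predict_amount(idfit, 50)$amount_pg, 50, tolerance = 1e-12)

  # below the lowest dilution point: detectable but not quantifiable
  low <- predict_amount(fit, 10^(-2 + 0.9 * log10(0.5)))
  expect_equal(low$status, "below_curve")
  high <- predict_amount(fit, 10^(-2 + 0.9 * log10(2000)))
  expect_equal(high$status, "above_curve")

  expect_error(predict_amount(fit, -1), "positive")
  flat <- suppressWarnings(fit_reference_curve(
    data.frame(amount_pg = rep(c(1, 10), each = 2), intensity = 5)))
  expect_error(predict_amount(flat, 5), "slope")
})

test_that("round-trip and monotonicity hold across the calibrated range", {
  crv <- generate_reference_curve("X", 10^seq(0, 3, length.out = 8),
                                  slope = 1.1, intercept = -1.5,
                                  noise_sd = 0)
  fit <- fit_reference_curve(crv)
  amounts <- 10^seq(0, 3, length.out = 23)
  back <- predict_amount(fit, 10^(fit$intercept + fit$slope * log10(amounts)))
  expect_equal(back$amount_pg, amounts, tolerance = 1e-9)
  # strictly increasing in intensity when slope > 0
  q <- sort(stats::runif(50, 1, 100))
  expect_true(all(diff(predict_amount(fit, q)$amount_pg) > 0))
  # rescaling all intensities by c shifts the intercept by log10(c) and
  # leaves predictions of rescaled queries unchanged
  crv2 <- crv
  crv2$intensity <- crv2$intensity * 37
  fit2 <- fit_reference_curve(crv2)
  expect_equal(fit2$intercept - fit$intercept, log10(37), tolerance = 1e-9)
  expect_equal(predict_amount(fit2, 5 * 37)$amount_pg,
               predict_amount(fit, 5)$amount_pg, tolerance = 1e-9)
})

test_that("noiseless mixture series are detected down to the smallest fraction", {
  lay <- assay_layout("EpCAM", "S1")
  ser <- generate_mixture_series(
    mixture_spec(c(0, 3, 6, 12, 25, 50, 100), positive_level = 500,
                 negative_level = 50, noise_cv = 0, seed = 1), lay)
  lod <- estimate_lod(ser)
  expect_equal(lod$lod_fraction, 3)
  expect_true(all(lod$detected[-1]))

  flat <- generate_mixture_series(
    mixture_spec(c(0, 3, 6), positive_level = 50, negative_level = 50,
                 noise_cv = 0, seed = 1), lay)
  expect_true(is.na(estimate_lod(flat)$lod_fraction))

  no_bg <- mixture_series(c(3, 6), matrix(1:4, 2))
  expect_error(estimate_lod(no_bg), "background")
})

test_that("reported LOD matches the brute-force fraction-by-fraction scan", {
  lay <- assay_layout("EpCAM", "S1")
  for (seed in 1:40) {
    sp <- mixture_spec(c(0, 3, 6, 12, 25, 50, 100), positive_level = 120,
                       negative_level = 50, noise_cv = 0.2, seed = seed)
    ser <- generate_mixture_series(sp, lay)
    for (k in c(2, 3, 5)) {
      got <- estimate_lod(ser, k = k, min_detect_reps = 2)$lod_fraction
      want <- lod_scan_oracle(ser$fractions, ser$intensities,
                              ser$background_stats$mean,
                              ser$background_stats$sd, k, 2)
      expect_identical(got, want)
    }
  }
})

test_that("raising k never enlarges the detected set", {
  lay <- assay_layout("EpCAM", "S1")
  for (seed in 1:20) {
    ser <- generate_mixture_series(
      mixture_spec(c(0, 3, 6, 12, 25, 50, 100), positive_level = 150,
                   negative_level = 50, noise_cv = 0.25, seed = seed), lay)
    prev <- NULL
    for (k in c(1, 2, 3, 5, 8)) {
      det <- estimate_lod(ser, k = k)$detected
      if (!is.null(prev)) expect_true(all(det <= prev))
      prev <- det
    }
  }
})

test_that("mixture linearity reports correlation, slope and degeneracy", {
  lay <- assay_layout("EpCAM", "S1")
  ser <- generate_mixture_series(
    mixture_spec(c(0, 25, 50, 100), positive_level = 110,
                 negative_level = 10, noise_cv = 0, seed = 1), lay)
  lin <- mixture_linearity(ser)
  expect_equal(lin$pearson_r, 1.0, tolerance = 1e-12)
  expect_equal(lin$slope, 1.0, tolerance = 1e-12)  # (110-10)/100 per percent

  const <- generate_mixture_series(
    mixture_spec(c(0, 50, 100), positive_level = 10, negative_level = 10,
                 noise_cv = 0, seed = 1), lay)
  expect_equal(mixture_linearity(const)$status, "not_applicable")
  expect_error(mixture_linearity(
    mixture_series(c(0, 100), matrix(1:4, 2))), "3 distinct")

  noisy <- generate_mixture_series(
    mixture_spec(c(0, 3, 6, 12, 25, 50, 100), positive_level = 1000,
                 negative_level = 50, noise_cv = 0.1, seed = 8), lay)
  lin2 <- mixture_linearity(noisy)
  expect_equal(lin2$pearson_r,
               cor(noisy$fractions, rowMeans(noisy$intensities)),
               tolerance = 1e-12)
})
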