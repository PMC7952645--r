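# A small masked grid with two segments for derivative/hull unit tests.
toy_mask <- spectral_mask(retained_range = c(400, 500),
                          excluded_intervals = list(c(440, 460)))
toy_wl <- c(400:439, 461:500)

test_that("reciprocal and log-reciprocal transforms follow their formulas", {
  m <- matrix(0.5, 2, length(toy_wl))
  expect_equal(apply_transform(m, "recip", toy_wl, toy_mask)$values,
               matrix(2, 2, length(toy_wl)))
  m1 <- matrix(1, 2, length(toy_wl))
  expect_equal(apply_transform(m1, "log_recip", toy_wl, toy_mask)$values,
               matrix(0, 2, length(toy_wl)))
  # reflectance floored before reciprocal: no infinities from zeros
  m0 <- matrix(c(0, 0.25), 1, length(toy_wl))
  expect_true(all(is.finite(apply_transform(m0, "recip", toy_wl, toy_mask)$values)))
})

test_that("the method table has exactly the nine ids", {
  expect_identical(transform_methods(),
                   c("R", "recip", "log_recip", "d1", "d1_recip",
                     "d1_log_recip", "CR", "MSC", "norm"))
  expect_error(apply_transform(matrix(1, 1, length(toy_wl)), "snv", toy_wl,
                               toy_mask))
})

test_that("first derivative is exact on constants, lines and quadratics", {
  p <- length(toy_wl)
  expect_equal(first_derivative(matrix(0.4, 3, p), toy_wl, toy_mask),
               matrix(0, 3, p))
  lin <- matrix(rep(0.001 * toy_wl, 2), 2, byrow = TRUE)
  d <- first_derivative(lin, toy_wl, toy_mask)
  expect_equal(d, matrix(0.001, 2, p), tolerance = 1e-12)
  quad <- matrix(1e-5 * toy_wl^2, 1)
  dq <- first_derivative(quad, toy_wl, toy_mask)
  seg <- pwcspec:::mask_segment_id(toy_wl, toy_mask)
  interior <- which(c(FALSE, diff(seg) == 0) & c(diff(seg) == 0, FALSE))
  # central difference of a quadratic is exact at interior points
  expect_equal(dq[1, interior], 2e-5 * toy_wl[interior], tolerance = 1e-10)
})

test_that("derivatives never cross the masked gap and ignore offsets", {
  p <- length(toy_wl)
  # a spectrum with a large jump exactly at the gap: derivative must not see it
  v <- matrix(c(rep(0.2, 40), rep(0.9, 40)), 1)
  d <- first_derivative(v, toy_wl, toy_mask)
  expect_equal(d, matrix(0, 1, p))
  x <- matrix(withr::with_seed(2, runif(p)), 1)
  expect_equal(first_derivative(x, toy_wl, toy_mask),
               first_derivative(x + 5, toy_wl, toy_mask), tolerance = 1e-12)
  expect_error(first_derivative(matrix(1, 1, 2), c(400, 401), toy_mask),
               "fewer than 3")
})

test_that("continuum removal divides by the exhaustive upper hull", {
  # printed toy spectrum at unit spacing
  y <- c(0.5, 0.2, 0.3, 0.25, 0.6)
  x <- 1:5
  mask1 <- spectral_mask(c(1, 5), list())
  cr <- continuum_removal(y, x, mask1)
  expect_equal(cr, y / oracle_upper_hull(x, y), tolerance = 1e-12)
  expect_true(all(cr > 0 & cr <= 1))
  expect_equal(cr[c(1, 5)], c(1, 1))  # anchored endpoints
  # a linear spectrum is its own hull
  lin <- 0.1 + 0.01 * x
  expect_equal(continuum_removal(lin, x, mask1), rep(1, 5), tolerance = 1e-12)
  expect_error(continuum_removal(c(0.2, -0.1, 0.3, 0.1, 0.2), x, mask1),
               "positive")
})

test_that("continuum removal matches the hull oracle per segment on random spectra", {
  p <- length(toy_wl)
  v <- matrix(withr::with_seed(3, runif(3 * p, 0.05, 0.8)), 3)
  cr <- continuum_removal(v, toy_wl, toy_mask)
  expect_true(all(cr <= 1 + 1e-12 & cr > 0))
  seg <- pwcspec:::mask_segment_id(toy_wl, toy_mask)
  for (s in unique(seg)) {
    idx <- which(seg == s)
    for (i in 1:3) {
      expect_equal(cr[i, idx],
                   v[i, idx] / oracle_upper_hull(toy_wl[idx], v[i, idx]),
                   tolerance = 1e-10)
      # hull touch points: at least the two segment endpoints map to 1
      expect_gte(sum(abs(cr[i, idx] - 1) < 1e-9), 2)
    }
  }
})

test_that("MSC inverts additive/multiplicative scatter against the reference", {
  p <- 40
  ref <- withr::with_seed(4, runif(p, 0.2, 0.6))
  # the reference itself is returned unchanged (a = 1, b = 0)
  expect_equal(drop(msc_correct(rbind(ref), ref)), ref, tolerance = 1e-12,
               ignore_attr = TRUE)
  # exact affine distortion is corrected exactly
  distorted <- rbind(2 * ref + 0.1)
  expect_equal(drop(msc_correct(distorted, ref)), ref, tolerance = 1e-12,
               ignore_attr = TRUE)
  # random samples agree with the per-sample simple-regression oracle
  X <- withr::with_seed(6, rbind(1.2 * ref + 0.05 + rnorm(p, sd = 0.01),
                                 0.7 * ref - 0.02 + rnorm(p, sd = 0.01)))
  out <- msc_correct(X, ref)
  for (i in 1:2) {
    fit <- lm(X[i, ] ~ ref)
    expect_equal(out[i, ], (X[i, ] - coef(fit)[1]) / coef(fit)[2],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # a constant sample has zero regression slope on a varying reference
  expect_error(msc_correct(rbind(rep(0.3, p)), ref), "slope")
  expect_error(msc_correct(rbind(ref), rep(0.5, p)), "reference")
})

test_that("peak normalization scales every sample to a unit maximum", {
  expect_equal(normalize_peak(matrix(0.4, 2, 5)), matrix(1, 2, 5))
  x <- withr::with_seed(7, matrix(runif(30, 0.1, 0.9), 2))
  n1 <- normalize_peak(x)
  expect_equal(apply(n1, 1, max), c(1, 1))
  # scale invariance and rank preservation
  expect_equal(normalize_peak(3 * x), n1, tolerance = 1e-12)
  for (i in 1:2) expect_equal(order(n1[i, ]), order(x[i, ]))
  expect_error(normalize_peak(matrix(-1, 1, 4)), "positive")
})

test_that("band-wise correlation matches the Pearson formula and flags", {
  y <- c(1, 3, 2, 5)
  v <- cbind(y, -y, c(2, 2, 2, 2), c(0.5, 1.9, 1.2, 3.1))
  co <- correlation_with_target(v, y)
  expect_equal(co$r[1], 1)
  expect_equal(co$r[2], -1)
  expect_equal(co$r[3], 0)
  expect_true(co$zero_variance[3])
  # hand-computed Pearson for the fourth band
  x4 <- v[, 4]
  r4 <- sum((x4 - mean(x4)) * (y - mean(y))) /
    sqrt(sum((x4 - mean(x4))^2) * sum((y - mean(y))^2))
  expect_equal(co$r[4], r4, tolerance = 1e-12)
  expect_true(all(co$r >= -1 & co$r <= 1))
  expect_error(correlation_with_target(v[1:2, ], y[1:2]), "3 samples")
})

test_that("preprocessing pipeline order is fixed and identity-transparent", {
  scene <- scene_params(wavelength_step = 5)
  ds <- generate_dataset(design_season_one(), scene, seed = 4)
  mask <- spectral_mask()
  tr <- preprocess_spectra(ds, "R", mask)
  manual <- apply_mask(sg_smooth(ds$reflectance), mask,
                       wavelengths_nm = ds$wavelengths_nm)
  expect_identical(tr$values, unname(manual[,]))
  expect_identical(tr$wavelengths_nm, attr(manual, "wavelengths_nm"))
  # MSC on validation data must reuse the calibration reference
  cal <- preprocess_spectra(ds, "MSC", mask)
  ds2 <- generate_dataset(design_season_two(), scene, seed = 5)
  val <- preprocess_spectra(ds2, "MSC", mask, reference = cal$reference)
  expect_identical(val$reference, cal$reference)
  sm <- apply_mask(sg_smooth(ds$reflectance), mask,
                   wavelengths_nm = ds$wavelengths_nm)
  expect_equal(cal$reference, unname(colMeans(sm)), tolerance = 1e-12)
})
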