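test_that("degenerate and limiting PLSR fits behave as specified", {
  prob <- tiny_problem(n = 15, p = 4, seed = 1)
  # constant response: zero coefficients, intercept = the constant
  fit0 <- fit_plsr(prob$X, rep(7, 15), n_lv = 2)
  expect_equal(fit0$b_coefficients, rep(0, 4))
  expect_equal(fit0$intercept, 7)
  expect_equal(unname(predict(fit0, prob$X)), rep(7, 15))
  # with n_lv = p on full-column-rank tall data, PLSR equals OLS
  fit <- fit_plsr(prob$X, prob$y, n_lv = 4)
  ols <- lm(prob$y ~ prob$X)
  expect_equal(unname(predict(fit, prob$X)), unname(fitted(ols)),
               tolerance = 1e-8)
  expect_error(fit_plsr(prob$X, prob$y, n_lv = 20), "n_lv")
})

test_that("the first weight vector is proportional to X'y and has unit norm", {
  prob <- tiny_problem(n = 10, p = 5, seed = 2)
  fit <- fit_plsr(prob$X, prob$y, n_lv = 3)
  Xc <- scale(prob$X, scale = FALSE)
  yc <- prob$y - mean(prob$y)
  w1 <- drop(crossprod(Xc, yc))
  expect_equal(fit$weight_vectors[, 1], w1 / sqrt(sum(w1^2)), tolerance = 1e-12)
  expect_equal(colSums(fit$weight_vectors^2), rep(1, 3), tolerance = 1e-12)
  expect_true(all(fit$explained_y_ss >= 0))
})

test_that("prediction follows the centering identities", {
  prob <- tiny_problem(n = 12, p = 5, seed = 3)
  fit <- fit_plsr(prob$X, prob$y, n_lv = 3)
  # predicting the centroid returns the mean response
  expect_equal(unname(predict(fit, fit$x_mean)), fit$y_mean, tolerance = 1e-10)
  # single sample equals the hand-computed dot product
  x1 <- prob$X[1, ]
  expect_equal(unname(predict(fit, x1)),
               fit$y_mean + sum((x1 - fit$x_mean) * fit$b_coefficients),
               tolerance = 1e-12)
  expect_error(predict(fit, matrix(0, 1, 4)), "bands")
})

test_that("the LOOCV curve equals the brute-force refit oracle", {
  prob <- tiny_problem(n = 8, p = 5, seed = 4, noise = 0.3)
  cv <- loocv_rmse_curve(prob$X, prob$y, A_max = 4)
  expect_length(cv$rmse_cv, 4)
  expect_equal(cv$rmse_cv, oracle_loocv(prob$X, prob$y, 4), tolerance = 1e-10)
  expect_equal(cv$chosen_lv, which.min(cv$rmse_cv))
  # the one-standard-error rule never chooses more LVs than the minimum
  cv1 <- loocv_rmse_curve(prob$X, prob$y, A_max = 4, rule = "onese")
  expect_lte(cv1$chosen_lv, cv$chosen_lv)
  expect_error(loocv_rmse_curve(prob$X, prob$y, A_max = 0), "A_max")
})

test_that("coefficients agree with an independent score-space predictor", {
  prob <- tiny_problem(n = 14, p = 7, seed = 5, noise = 0.5)
  for (a in c(1, 3, 5)) {
    fit <- fit_plsr(prob$X, prob$y, n_lv = a)
    ref <- oracle_pls_fit(prob$X, prob$y, a)
    expect_equal(unname(predict(fit, prob$X)),
                 unname(oracle_pls_predict(ref, prob$X)), tolerance = 1e-9)
  }
})

test_that("calibration RMSE is non-increasing in the number of LVs", {
  prob <- tiny_problem(n = 20, p = 10, seed = 6, noise = 1)
  rmse <- vapply(1:8, function(a) {
    fit <- fit_plsr(prob$X, prob$y, a)
    sqrt(mean((predict(fit, prob$X) - prob$y)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) <= 1e-10))
})

test_that("VIP satisfies Eq-style identities and the literal formula", {
  prob <- tiny_problem(n = 16, p = 9, seed = 7, noise = 0.4)
  fit <- fit_plsr(prob$X, prob$y, n_lv = 4)
  vip <- vip_scores(fit)
  expect_true(all(vip >= 0))
  # sum of squared VIP equals the band count, for any fit
  expect_equal(sum(vip^2), 9, tolerance = 1e-10)
  # literal re-evaluation from the stored weights and explained SS
  ss <- fit$explained_y_ss
  lit <- sqrt(9 * as.vector(fit$weight_vectors^2 %*% ss) / sum(ss))
  expect_equal(vip, lit, tolerance = 1e-12)
  # single orthogonal informative band: its VIP is sqrt(p), others 0
  X <- contr.helmert(12)[, 1:4]  # centered, mutually orthogonal columns
  y <- X[, 2] * 2 + 1
  fit1 <- fit_plsr(X, y, n_lv = 1)
  v1 <- vip_scores(fit1)
  expect_equal(v1[2], 2, tolerance = 1e-9)
  expect_equal(v1[-2], rep(0, 3), tolerance = 1e-9)
  # mean VIP^2 = 1 guarantees a non-empty VIP>1 screen on non-degenerate fits
  expect_true(any(vip >= 1))
})

test_that("model serialization round-trips predictions bit-exactly", {
  prob <- tiny_problem(n = 12, p = 6, seed = 8)
  fit <- fit_plsr(prob$X, prob$y, n_lv = 3, wavelengths_nm = 101:106)
  path <- withr::local_tempfile(fileext = ".txt")
  write_plsr_model(fit, path)
  fit2 <- read_plsr_model(path)
  expect_identical(predict(fit2, prob$X), predict(fit, prob$X))
  expect_identical(fit2$b_coefficients, fit$b_coefficients)
})
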