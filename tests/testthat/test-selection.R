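test_that("the B+VIP screen applies the union rule literally", {
  prob <- tiny_problem(n = 30, p = 8, seed = 1, noise = 0.5)
  fit <- fit_plsr(prob$X, prob$y, n_lv = 3, wavelengths_nm = 501:508)
  sel <- screen_b_vip(fit)
  # independent scan of the quoted rule
  vip <- vip_scores(fit)
  b <- abs(fit$b_coefficients)
  expect_identical(sel$selected_idx, which(vip > 1 | b > mean(b)))
  expect_equal(sel$selected_bands, (501:508)[sel$selected_idx])
  expect_gt(length(sel$selected_idx), 0)
})

test_that("the screen degrades gracefully to a single criterion", {
  # hand-built model objects isolate the rule from the fitting
  mk <- function(W, ss, b) {
    structure(list(weight_vectors = W, explained_y_ss = ss,
                   b_coefficients = b, band_count = nrow(W), n_lv = ncol(W),
                   wavelengths_nm = seq_len(nrow(W))),
              class = "plsr_model")
  }
  # all |b| equal: none exceeds the mean, selection is VIP-only
  W <- cbind(c(1, 0, 0, 0) )  # VIP = (2,0,0,0)
  m1 <- mk(W, 1, rep(0.3, 4))
  expect_identical(screen_b_vip(m1)$selected_idx, 1L)
  # VIP identically 1 (symmetric weights): selection is b-only
  W2 <- cbind(rep(0.5, 4))
  m2 <- mk(W2, 1, c(0.9, 0.1, 0.1, 0.1))
  expect_identical(screen_b_vip(m2)$selected_idx, 1L)
})

test_that("stepwise regression recovers a noise-free single-band response", {
  withr::with_seed(2, {
    X <- matrix(rnorm(40 * 6), 40, 6)
    y <- 2 * X[, 4]
  })
  sel <- stepwise_select(X, y, wavelengths_nm = 601:606)
  expect_identical(sel$selected_bands, 604)
})

test_that("stepwise regression selects nothing when there is no signal", {
  sizes <- vapply(1:5, function(seed) {
    withr::with_seed(seed, {
      X <- matrix(rnorm(30 * 8), 30, 8)
      y <- rnorm(30)
    })
    length(stepwise_select(X, y)$selected_bands)
  }, numeric(1))
  expect_lte(mean(sizes), 1)  # null behaviour: empty or near-empty
})

test_that("stepwise trajectory matches the add1/drop1 oracle on 6 candidates", {
  for (seed in 1:4) {
    prob <- tiny_problem(n = 25, p = 6, seed = seed, informative = c(1, 3),
                         noise = 0.4)
    sel <- stepwise_select(prob$X, prob$y)
    ref <- oracle_stepwise(prob$X, prob$y)
    expect_identical(sel$selected_idx, as.integer(ref$included))
    # identical action sequences, step by step
    acts <- vapply(sel$diagnostics$trajectory, `[[`, character(1), "action")
    bands <- vapply(sel$diagnostics$trajectory, `[[`, numeric(1), "band")
    ref_acts <- vapply(ref$trajectory, `[`, character(1), 1)
    ref_bands <- as.integer(sub("b", "", vapply(ref$trajectory, `[`,
                                                character(1), 2)))
    expect_identical(acts, ref_acts)
    expect_identical(as.integer(bands), ref_bands)
  }
})

test_that("SPA orders orthogonal columns by residual norm and skips duplicates", {
  # centered orthogonal columns with distinct norms
  Q <- qr.Q(qr(withr::with_seed(3, matrix(rnorm(20 * 4), 20, 4))))
  X <- Q %*% diag(c(4, 3, 2, 1))
  chain <- pwcspec:::spa_chain(X, start = 1L, max_size = 4L, colSums(X^2))
  expect_identical(chain, c(1L, 2L, 3L, 4L))  # decreasing residual norms
  # an exact duplicate is never chosen while its twin is in the chain
  Xd <- cbind(X, X[, 2])
  chain_d <- pwcspec:::spa_chain(Xd, start = 2L, max_size = 5L, colSums(Xd^2))
  expect_false(all(c(2L, 5L) %in% chain_d))
})

test_that("the SPA chain equals the lm-projection oracle", {
  withr::with_seed(4, {
    X <- matrix(rnorm(10 * 5), 10, 5)
  })
  for (start in 1:3) {
    chain <- pwcspec:::spa_chain(X, start = as.integer(start), max_size = 4L,
                                 colSums(X^2))
    expect_identical(as.integer(chain), as.integer(oracle_spa_chain(X, start, 4)))
  }
})

test_that("the PRESS identity reproduces brute-force OLS LOOCV", {
  withr::with_seed(5, {
    X <- matrix(rnorm(15 * 4), 15, 4)
    y <- X[, 1] - X[, 3] + rnorm(15, sd = 0.5)
  })
  press <- pwcspec:::press_rmse_prefix(X, y)
  for (s in 1:4)
    expect_equal(press[s], oracle_ols_loocv(X[, 1:s, drop = FALSE], y),
                 tolerance = 1e-10)
})

test_that("SPA selects a small informative subset and honours preconditions", {
  prob <- tiny_problem(n = 25, p = 10, seed = 6, informative = c(2, 7),
                       noise = 0.2)
  sel <- spa_select(prob$X, prob$y, wavelengths_nm = 701:710, max_size = 6)
  expect_true(all(c(702, 707) %in% sel$selected_bands))
  expect_lte(length(sel$selected_bands), 6)
  expect_equal(sel$diagnostics$chosen_size,
               which.min(sel$diagnostics$rmsecv_by_size))
  expect_error(spa_select(prob$X, prob$y, max_size = 0), "max_size")
})

test_that("random frog is deterministic and its forward phase tracks the RMSE minimum", {
  prob <- tiny_problem(n = 30, p = 12, seed = 7, informative = c(1, 5),
                       noise = 0.5)
  s1 <- random_frog_select(prob$X, prob$y, n_iterations = 150, seed = 99)
  s2 <- random_frog_select(prob$X, prob$y, n_iterations = 150, seed = 99)
  expect_identical(s1$selected_bands, s2$selected_bands)
  expect_identical(s1$diagnostics$frequency, s2$diagnostics$frequency)
  curve <- s1$diagnostics$rmse_by_rank
  expect_equal(s1$diagnostics$chosen_size, which.min(curve))
  expect_error(random_frog_select(prob$X, prob$y, n_iterations = 50, seed = 1),
               ">= 100")
  expect_error(random_frog_select(prob$X, prob$y, n_iterations = 150), "seed")
})

test_that("random frog frequencies separate planted bands from noise", {
  # 5 informative bands among 45 noise bands, per-seed medians vs 90th pct
  ok <- vapply(1:5, function(seed) {
    withr::with_seed(seed, {
      X <- matrix(rnorm(40 * 50), 40, 50)
      y <- drop(X[, 1:5] %*% c(3, 3, 2, 2, 2) + rnorm(40, sd = 0.5))
    })
    sel <- random_frog_select(X, y, n_iterations = 1000, seed = seed + 100)
    freq <- sel$diagnostics$frequency
    median(freq[1:5]) > quantile(freq[6:50], 0.9)
  }, logical(1))
  expect_true(all(ok))
})

test_that("UVE retains an exact response copy and rejects pure noise", {
  withr::with_seed(8, {
    X <- matrix(rnorm(30 * 10), 30, 10)
    y <- rnorm(30)
    X[, 4] <- y  # exact linear copy of the response
  })
  sel <- uve_select(X, y, wavelengths_nm = 801:810, seed = 1)
  expect_true(804 %in% sel$selected_bands)
  expect_gt(abs(sel$diagnostics$stability[4]), sel$diagnostics$threshold)
  # pure-noise candidates: empty or near-empty selection across seeds
  sizes <- vapply(1:3, function(seed) {
    withr::with_seed(seed + 20, {
      Xn <- matrix(rnorm(25 * 12), 25, 12)
      yn <- rnorm(25)
    })
    length(uve_select(Xn, yn, seed = seed)$selected_bands)
  }, numeric(1))
  expect_lte(mean(sizes), 2)
})

test_that("UVE stability matches the explicit leave-one-out bookkeeping oracle", {
  prob <- tiny_problem(n = 12, p = 4, seed = 9, noise = 0.3)
  sel <- uve_select(prob$X, prob$y, seed = 3)
  a <- sel$diagnostics$n_lv
  # rebuild the augmented matrix exactly as uve_select does
  noise <- withr::with_seed(3, matrix(rnorm(12 * 4), 12, 4)) *
    (1e-10 * mean(abs(prob$X)))
  Xa <- cbind(prob$X, noise)
  B <- t(vapply(seq_len(12), function(i) {
    ref <- oracle_pls_fit(Xa[-i, , drop = FALSE], prob$y[-i], a)
    oracle_pls_coefs(ref)
  }, numeric(8)))
  stab <- colMeans(B) / apply(B, 2, sd)
  expect_equal(sel$diagnostics$stability, stab[1:4], tolerance = 1e-6)
  expect_equal(sel$diagnostics$threshold, max(abs(stab[5:8])), tolerance = 1e-6)
})

test_that("full-scale selection: subsets, reductions and refit quality", {
  runs <- acceptance_runs()
  for (run in runs) {
    screen <- run$selections$BVIP$selected_bands
    for (m in c("BVIP_SR", "BVIP_SPA", "BVIP_RF", "BVIP_UVE")) {
      sel <- run$selections[[m]]$selected_bands
      expect_gt(length(sel), 0)
      expect_true(all(sel %in% screen),
                  label = sprintf("%s subset of screen (seed %d)", m, run$seed))
    }
    # refitting on any selected set stays near the full-spectrum model
    expect_true(all(abs(run$r2_cal - run$r2_cal_full) <= 0.15),
                label = sprintf("refit R2 within 0.15 (seed %d)", run$seed))
  }
})
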