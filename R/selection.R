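#' Band selection result container
#'
#' @param method_id One of `BVIP`, `BVIP_SR`, `BVIP_SPA`, `BVIP_RF`,
#'   `BVIP_UVE`.
#' @param selected_bands Ordered wavelengths (nm) of the selected bands.
#' @param selected_idx Indices of the selected bands in the candidate
#'   matrix the method operated on.
#' @param diagnostics Method-specific diagnostics list.
#' @param seed Seed used by stochastic methods (`NA` otherwise).
#' @return An object of class `selection_result`.
#' @export
selection_result <- function(method_id, selected_bands, selected_idx,
                             diagnostics = list(), seed = NA_integer_) {
  structure(
    list(method_id = method_id,
         selected_bands = as.numeric(selected_bands),
         selected_idx = as.integer(selected_idx),
         diagnostics = diagnostics,
         seed = seed),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result [%s]: %d bands\n",
              x$method_id, length(x$selected_bands)))
  if (length(x$selected_bands))
    cat("  ", paste(utils::head(x$selected_bands, 12), collapse = ", "),
        if (length(x$selected_bands) > 12) "...", "\n")
  invisible(x)
}

#' Initial B-coefficient / VIP screen
#'
#' Union rule: a band passes if its VIP score exceeds 1 *or* the absolute
#' value of its B-coefficient exceeds the mean absolute B-coefficient.
#' This deliberately permissive screen defines the candidate set on which
#' the four combined selection methods operate.
#'
#' @param model A fitted `plsr_model` (its `wavelengths_nm` must be set).
#' @param vip_threshold VIP cut-off (default 1).
#' @return A `selection_result` with `method_id = "BVIP"`; diagnostics
#'   hold the VIP scores and the B-coefficient criterion.
#' @export
screen_b_vip <- function(model, vip_threshold = 1) {
  stopifnot(inherits(model, "plsr_model"))
  vip <- vip_scores(model)  # errors on degenerate models
  b <- abs(model$b_coefficients)
  b_crit <- mean(b)
  keep <- which(vip > vip_threshold | b > b_crit)
  wl <- model$wavelengths_nm %||% seq_len(model$band_count)
  selection_result(
    "BVIP", wl[keep], keep,
    diagnostics = list(vip = vip, abs_b = b, b_criterion = b_crit,
                       vip_threshold = vip_threshold)
  )
}

#' Bidirectional stepwise regression
#'
#' Forward/backward elimination on the candidate bands: starting from an
#' empty model, the candidate with the smallest partial-F p-value is
#' added while that p-value is below `p_enter`; after each addition any
#' included band whose coefficient p-value is at or above `p_remove` is
#' removed. The procedure stops when no addition or removal changes the
#' model. Deterministic; p-value ties resolve toward the lowest
#' wavelength. Near-singular candidates (residual norm ~ 0 given the
#' current model) are skipped with a logged note.
#'
#' @param X Candidate matrix (samples x candidate bands), normally the
#'   B+VIP-screened columns.
#' @param y Response vector.
#' @param wavelengths_nm Candidate wavelengths.
#' @param p_enter,p_remove Entry (0.01) and removal (0.05) thresholds.
#' @param max_size Safety cap on model size (default `n - 3`).
#' @return A `selection_result` (`BVIP_SR`) with the add/remove
#'   trajectory and final coefficient p-values in the diagnostics.
#' @export
stepwise_select <- function(X, y, wavelengths_nm = NULL,
                            p_enter = 0.01, p_remove = 0.05,
                            max_size = NULL) {
  X <- assert_matrix_like(X, "X")
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  wl <- wavelengths_nm %||% seq_len(p)
  max_size <- as.integer(max_size %||% (n - 3L))
  ord <- order(wl)  # scan in wavelength order so ties pick the lowest
  included <- integer(0)
  trajectory <- list()
  skipped <- integer(0)
  repeat {
    changed <- FALSE
    # forward step
    if (length(included) < max_size && length(included) < p) {
      Q <- qr.Q(qr(cbind(1, X[, included, drop = FALSE])))
      ry <- y - Q %*% crossprod(Q, y)
      rss0 <- sum(ry^2)
      df <- n - length(included) - 2L
      if (df >= 1L && rss0 > 1e-20) {
        cand <- setdiff(ord, included)
        Xr <- X[, cand, drop = FALSE]
        Xr <- Xr - Q %*% crossprod(Q, Xr)
        ssx <- colSums(Xr^2)
        ok <- ssx > 1e-10 * colSums(X[, cand, drop = FALSE]^2)
        skipped <- union(skipped, cand[!ok])
        if (any(ok)) {
          rho2 <- (as.vector(crossprod(Xr, ry))^2) / (ssx * rss0)
          rho2[!ok] <- -Inf
          rho2 <- pmin(rho2, 1 - 1e-15)
          pv <- pf(rho2 * df / (1 - rho2), 1, df, lower.tail = FALSE)
          pv[!ok] <- Inf
          j <- which.min(pv)  # cand is wavelength-ordered: ties -> lowest wl
          if (pv[j] < p_enter) {
            included <- c(included, cand[j])
            trajectory <- c(trajectory, list(list(action = "add",
                                                  band = wl[cand[j]],
                                                  p_value = pv[j])))
            changed <- TRUE
          }
        }
      }
    }
    # backward sweep
    repeat {
      if (length(included) == 0L) break
      fit <- lm(y ~ X[, included, drop = FALSE])
      sm <- suppressWarnings(summary(fit))$coefficients
      pv <- rep(1, length(included))  # aliased coefficients count as removable
      rn <- !is.na(coef(fit)[-1])
      pv[rn] <- sm[-1, 4][seq_len(sum(rn))]
      worst <- which(pv >= p_remove)
      if (!length(worst)) break
      # remove the largest p-value; on ties keep the lowest wavelength
      w <- worst[order(-pv[worst], -wl[included[worst]])][1]
      trajectory <- c(trajectory, list(list(action = "remove",
                                            band = wl[included[w]],
                                            p_value = pv[w])))
      included <- included[-w]
      changed <- TRUE
    }
    if (!changed) break
  }
  included <- sort(included)
  final_p <- if (length(included)) {
    sm <- suppressWarnings(summary(lm(y ~ X[, included, drop = FALSE])))$coefficients
    sm[-1, 4]
  } else numeric(0)
  selection_result(
    "BVIP_SR", wl[included], included,
    diagnostics = list(trajectory = trajectory, p_enter = p_enter,
                       p_remove = p_remove, p_values = final_p,
                       skipped_near_singular = wl[skipped])
  )
}

#' Successive projections algorithm
#'
#' Forward selection minimizing collinearity: starting from each
#' candidate band in turn, the chain repeatedly adds the band whose
#' column has the largest norm after projection onto the orthogonal
#' complement of the span of the bands already in the chain. Every
#' (start, size) chain with `size <= max_size` is scored by the
#' leave-one-out RMSE of a multiple linear regression on the chain
#' (computed via the exact PRESS identity), and the globally best chain
#' is returned. Ties resolve toward smaller chains, then lower starting
#' wavelengths.
#'
#' @param X Candidate matrix.
#' @param y Response vector.
#' @param wavelengths_nm Candidate wavelengths.
#' @param max_size Largest chain length, default `min(30, n - 2)`.
#' @return A `selection_result` (`BVIP_SPA`); diagnostics hold the
#'   winning projection order and its per-size RMSECV curve.
#' @export
spa_select <- function(X, y, wavelengths_nm = NULL, max_size = NULL) {
  X <- assert_matrix_like(X, "X")
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  wl <- wavelengths_nm %||% seq_len(p)
  max_size <- as.integer(max_size %||% min(30L, n - 2L))
  if (max_size < 1L) stopf("`max_size` must be >= 1")
  max_size <- min(max_size, p, n - 2L)
  col_ss <- colSums(X^2)
  best <- list(rmse = Inf, chain = integer(0), size = 0L, curve = numeric(0))
  for (start in seq_len(p)) {
    chain <- spa_chain(X, start, max_size, col_ss)
    curve <- press_rmse_prefix(X[, chain, drop = FALSE], y)
    s <- which.min(curve)  # ties -> smaller size
    better <- curve[s] < best$rmse ||
      (curve[s] == best$rmse &&
         (s < best$size || (s == best$size && wl[chain[1]] < wl[best$chain[1]])))
    if (better)
      best <- list(rmse = curve[s], chain = chain, size = s, curve = curve)
  }
  sel <- sort(best$chain[seq_len(best$size)])
  selection_result(
    "BVIP_SPA", wl[sel], sel,
    diagnostics = list(projection_order = wl[best$chain],
                       rmsecv_by_size = best$curve,
                       chosen_size = best$size, max_size = max_size)
  )
}

# Projection chain from one starting column: repeatedly orthogonalize all
# columns against the last chosen direction and take the largest residual
# norm. Columns that become numerically dependent are never chosen.
#' @noRd
spa_chain <- function(X, start, max_size, col_ss) {
  p <- ncol(X)
  Xr <- X
  chain <- integer(max_size)
  chain[1L] <- start
  chosen <- rep(FALSE, p)
  chosen[start] <- TRUE
  u <- Xr[, start]
  k <- 1L
  while (k < max_size) {
    uu <- sum(u^2)
    if (uu < 1e-20) break
    Xr <- Xr - u %*% (crossprod(u, Xr) / uu)
    norms <- colSums(Xr^2)
    norms[chosen | norms <= 1e-10 * col_ss] <- -Inf
    j <- which.max(norms)  # ties -> first (lowest wavelength order assumed)
    if (!is.finite(norms[j])) break
    k <- k + 1L
    chain[k] <- j
    chosen[j] <- TRUE
    u <- Xr[, j]
  }
  chain[seq_len(k)]
}

# Exact LOOCV RMSE of OLS (with intercept) for every prefix of the given
# column order, via the PRESS identity e_i / (1 - h_ii) on the nested QR.
#' @noRd
press_rmse_prefix <- function(Xchain, y) {
  n <- nrow(Xchain)
  Z <- cbind(1, Xchain)
  qz <- qr(Z)
  Q <- qr.Q(qz)
  r1 <- abs(diag(qr.R(qz)))
  Qty <- crossprod(Q, y)
  out <- rep(NA_real_, ncol(Xchain))
  resid <- y - Q[, 1L, drop = FALSE] %*% Qty[1L]
  h <- Q[, 1L]^2
  for (s in seq_len(ncol(Xchain))) {
    k <- s + 1L
    if (k > qz$rank || r1[k] < 1e-10 * r1[1]) break  # rank-deficient prefix
    resid <- resid - Q[, k, drop = FALSE] * Qty[k]
    h <- h + Q[, k]^2
    if (k >= n) break  # saturated model: LOOCV undefined
    out[s] <- sqrt(mean((resid / (1 - h))^2))
  }
  out
}

#' Random frog band selection
#'
#' Two-phase stochastic selector. Phase 1 is a reversible-jump style
#' subset search: from the current subset a resized candidate subset is
#' proposed (growing by random unchosen bands, shrinking to the bands
#' with the largest absolute PLS coefficients, or swapping one member),
#' scored by the leave-one-out RMSE of an inner PLS model, and accepted
#' if it improves — otherwise accepted with probability equal to the
#' performance ratio. Each iteration the members of the current subset
#' are tallied, yielding per-band selection frequencies. Phase 2 ranks
#' bands by frequency (ties toward lower wavelengths) and adds them one
#' at a time into a PLS model whose LV count is chosen by an inner
#' LOOCV; the returned subset is the frequency-ranked prefix with the
#' minimum LOOCV RMSE. Prefix evaluation stops early once `patience`
#' consecutive prefixes fail to improve the incumbent minimum.
#'
#' @param X Candidate matrix.
#' @param y Response vector.
#' @param wavelengths_nm Candidate wavelengths.
#' @param n_iterations Phase-1 iterations (>= 100; default 1000).
#' @param seed Mandatory integer seed; identical seeds give identical
#'   results.
#' @param init_size Initial subset size (callers typically pass the LV
#'   count of the screening model).
#' @param n_lv_inner Largest LV count of the inner PLS models.
#' @param patience Phase-2 early-stopping patience.
#' @return A `selection_result` (`BVIP_RF`); diagnostics hold the
#'   selection frequencies, the phase-2 RMSE curve and the acceptance
#'   count.
#' @export
random_frog_select <- function(X, y, wavelengths_nm = NULL,
                               n_iterations = 1000L, seed,
                               init_size = 5L, n_lv_inner = 5L,
                               patience = 30L) {
  X <- assert_matrix_like(X, "X")
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  wl <- wavelengths_nm %||% seq_len(p)
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 100L) stopf("`n_iterations` must be >= 100")
  if (missing(seed)) stopf("`seed` is mandatory for random frog")
  init_size <- max(1L, min(as.integer(init_size), p, n - 2L))
  inner_rmse <- function(idx) {
    A <- min(n_lv_inner, length(idx), n - 2L)
    pls1_loocv(X[, idx, drop = FALSE], y, A)$rmse[A]
  }
  res <- with_seed(seed, {
    counts <- numeric(p)
    cur <- sort(sample.int(p, init_size))
    cur_rmse <- inner_rmse(cur)
    accepted <- 0L
    for (it in seq_len(n_iterations)) {
      s_new <- max(1L, min(p, n - 2L,
                           round(rnorm(1, length(cur), max(1, 0.3 * length(cur))))))
      if (s_new > length(cur)) {
        pool <- setdiff(seq_len(p), cur)
        cand <- sort(c(cur, sample(pool, min(s_new - length(cur), length(pool)))))
      } else if (s_new < length(cur)) {
        b <- pls1_coef(pls1_engine(scale(X[, cur, drop = FALSE], scale = FALSE),
                                   y - mean(y),
                                   min(n_lv_inner, length(cur), n - 2L)))
        cand <- sort(cur[order(-abs(b))][seq_len(s_new)])
      } else {
        pool <- setdiff(seq_len(p), cur)
        cand <- if (length(pool)) {
          drop_i <- sample.int(length(cur), 1L)
          sort(c(cur[-drop_i], sample(pool, 1L)))
        } else cur
      }
      cand_rmse <- inner_rmse(cand)
      if (cand_rmse <= cur_rmse || runif(1) < cur_rmse / cand_rmse) {
        cur <- cand
        cur_rmse <- cand_rmse
        accepted <- accepted + 1L
      }
      counts[cur] <- counts[cur] + 1
    }
    list(counts = counts, accepted = accepted)
  })
  freq <- res$counts / n_iterations
  rank_order <- order(-freq, wl)
  # phase 2: forward over the frequency ranking, LV by inner LOOCV
  rmse_curve <- rep(NA_real_, p)
  best_s <- 1L
  best_rmse <- Inf
  for (s in seq_len(p)) {
    idx <- rank_order[seq_len(s)]
    A <- min(n_lv_inner * 2L, s, n - 2L)
    rmse_curve[s] <- min(pls1_loocv(X[, idx, drop = FALSE], y, A)$rmse)
    if (rmse_curve[s] < best_rmse) {
      best_rmse <- rmse_curve[s]
      best_s <- s
    } else if (s - best_s >= patience) break
  }
  sel <- sort(rank_order[seq_len(best_s)])
  selection_result(
    "BVIP_RF", wl[sel], sel, seed = as.integer(seed),
    diagnostics = list(frequency = freq, rank_order = wl[rank_order],
                       rmse_by_rank = rmse_curve[!is.na(rmse_curve)],
                       chosen_size = best_s,
                       n_iterations = n_iterations,
                       accepted = res$accepted)
  )
}

#' Uninformative variable elimination
#'
#' A noise block with as many columns as candidates (standard-normal
#' entries scaled to `1e-10` of the mean absolute spectral value) is
#' appended to the candidate matrix. A PLS model (LV count chosen by
#' LOOCV on the augmented matrix) is refit leaving each sample out in
#' turn, collecting the per-leave-out B-coefficients; the stability of a
#' variable is the mean of its coefficients divided by their standard
#' deviation. Real bands are retained when their absolute stability
#' exceeds the largest absolute stability observed among the noise
#' columns. A variable with zero coefficient spread gets signed-infinite
#' stability and is always retained.
#'
#' @param X Candidate matrix.
#' @param y Response vector.
#' @param wavelengths_nm Candidate wavelengths.
#' @param seed Seed for the noise block.
#' @param noise_scale Relative magnitude of the noise block.
#' @param n_lv LV count of the augmented PLS model. The pipeline passes
#'   the screening model's LV count (the classical protocol); when `NULL`
#'   the count is re-chosen by LOOCV on the augmented matrix, which tends
#'   to overfit per-band coefficients and prune far more aggressively.
#' @param A_max Largest LV count scanned when `n_lv` is `NULL`.
#' @return A `selection_result` (`BVIP_UVE`); diagnostics hold the
#'   stability coefficients of bands and noise and the threshold.
#' @export
uve_select <- function(X, y, wavelengths_nm = NULL, seed = 1L,
                       noise_scale = 1e-10, n_lv = NULL, A_max = NULL) {
  X <- assert_matrix_like(X, "X")
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  wl <- wavelengths_nm %||% seq_len(p)
  noise <- with_seed(seed, matrix(rnorm(n * p), n, p)) *
    (noise_scale * mean(abs(X)))
  Xa <- cbind(X, noise)
  a_star <- if (is.null(n_lv)) {
    A <- min(as.integer(A_max %||% 15L), n - 2L, ncol(Xa))
    which.min(pls1_loocv(Xa, y, A)$rmse)
  } else min(as.integer(n_lv), n - 2L, ncol(Xa))
  B <- matrix(0, n, 2L * p)
  for (i in seq_len(n)) {
    Xi <- Xa[-i, , drop = FALSE]
    yi <- y[-i]
    B[i, ] <- pls1_coef(pls1_engine(sweep(Xi, 2L, colMeans(Xi)),
                                    yi - mean(yi), a_star))
  }
  mu <- colMeans(B)
  sdv <- apply(B, 2L, sd)
  stab <- ifelse(sdv == 0, sign(mu) * Inf, mu / sdv)
  threshold <- max(abs(stab[(p + 1L):(2L * p)]))
  keep <- which(abs(stab[seq_len(p)]) > threshold)
  selection_result(
    "BVIP_UVE", wl[keep], keep, seed = as.integer(seed),
    diagnostics = list(stability = stab[seq_len(p)],
                       noise_stability = stab[(p + 1L):(2L * p)],
                       threshold = threshold, n_lv = a_star)
  )
}

#' Serialize a selection result
#'
#' Writes the selected wavelengths as a one-column CSV and the
#' diagnostics (seeds, thresholds, curves) as a JSON sidecar
#' (`<path>.json`).
#'
#' @param x A `selection_result`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_selection_result <- function(x, path) {
  stopifnot(inherits(x, "selection_result"))
  data.table::fwrite(data.table::data.table(wavelength_nm = x$selected_bands),
                     path)
  side <- x$diagnostics
  side$method_id <- x$method_id
  side$seed <- x$seed
  side <- side[!vapply(side, is.list, logical(1))]  # flat fields only
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
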