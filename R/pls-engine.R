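# Internal PLS1 (single-response) NIPALS engine.
#
# Operates on pre-centered X and y; no variance scaling. For a single
# response NIPALS needs no inner iteration: each component is
#   w = X'y / ||X'y||,  t = X w,  p = X't / t't,  q = t'y / t't,
# followed by deflation X <- X - t p', y <- y - q t. The weight vectors
# have unit norm; the explained sum of squares of y by component m is
# q_m^2 * t_m' t_m.
#
# Returns loadings for components 1..A (truncated early if X'y or t
# degenerates), from which regression coefficients for any component
# count a <= A follow via B_a = W_a (P_a' W_a)^{-1} q_a; P'W is unit
# upper triangular, so the solve is a backsolve.

#' @noRd
pls1_engine <- function(Xc, yc, A) {
  p <- ncol(Xc)
  A <- min(A, nrow(Xc) - 1L, p)
  W <- matrix(0, p, A)
  P <- matrix(0, p, A)
  q <- numeric(A)
  ss <- numeric(A)
  a <- 0L
  X <- Xc
  y <- yc
  for (m in seq_len(A)) {
    w <- crossprod(X, y)
    nw <- sqrt(sum(w * w))
    if (!is.finite(nw) || nw < 1e-12) break
    w <- w / nw
    t <- X %*% w
    tt <- sum(t * t)
    if (tt < 1e-12) break
    pm <- crossprod(X, t) / tt
    qm <- sum(t * y) / tt
    X <- X - tcrossprod(t, pm)
    y <- y - qm * t
    a <- m
    W[, m] <- w
    P[, m] <- pm
    q[m] <- qm
    ss[m] <- qm * qm * tt
  }
  if (a == 0L)
    return(list(W = matrix(0, p, 0), P = matrix(0, p, 0),
                q = numeric(0), ss = numeric(0), n_lv = 0L))
  list(W = W[, seq_len(a), drop = FALSE], P = P[, seq_len(a), drop = FALSE],
       q = q[seq_len(a)], ss = ss[seq_len(a)], n_lv = a)
}

# Regression coefficients (centered scale) for a given component count.
#' @noRd
pls1_coef <- function(fit, a = fit$n_lv) {
  if (a == 0L) return(numeric(nrow(fit$W)))
  R <- crossprod(fit$P[, seq_len(a), drop = FALSE],
                 fit$W[, seq_len(a), drop = FALSE])
  z <- backsolve(R, fit$q[seq_len(a)])
  drop(fit$W[, seq_len(a), drop = FALSE] %*% z)
}

# Coefficient matrix for all component counts 1..n_lv (p x n_lv).
#' @noRd
pls1_coef_all <- function(fit) {
  p <- nrow(fit$W)
  if (fit$n_lv == 0L) return(matrix(0, p, 0))
  out <- matrix(0, p, fit$n_lv)
  R <- crossprod(fit$P, fit$W)
  for (a in seq_len(fit$n_lv)) {
    z <- backsolve(R[seq_len(a), seq_len(a), drop = FALSE], fit$q[seq_len(a)])
    out[, a] <- fit$W[, seq_len(a), drop = FALSE] %*% z
  }
  out
}

# Brute-force leave-one-out RMSE for component counts 1..A.
# For each held-out sample the model is refit from scratch on the
# remaining rows (fresh centering included); no shortcut formulas.
# Returns a list(rmse = numeric(A), pred = n x A matrix).
#' @noRd
pls1_loocv <- function(X, y, A) {
  n <- nrow(X)
  A <- min(A, n - 2L, ncol(X))
  if (A < 1L) stopf("too few samples for cross-validation")
  pred <- matrix(NA_real_, n, A)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    yi <- y[-i]
    xm <- colMeans(Xi)
    ym <- mean(yi)
    fit <- pls1_engine(sweep(Xi, 2L, xm), yi - ym, A)
    if (fit$n_lv == 0L) {
      pred[i, ] <- ym
      next
    }
    B <- pls1_coef_all(fit)
    ph <- ym + drop((X[i, ] - xm) %*% B)
    pred[i, seq_len(fit$n_lv)] <- ph
    if (fit$n_lv < A) pred[i, (fit$n_lv + 1L):A] <- ph[fit$n_lv]
  }
  err <- pred - y
  list(rmse = sqrt(colMeans(err^2)), pred = pred)
}

# Minimum LOOCV RMSE over component counts 1..A (value and argmin).
#' @noRd
pls1_loocv_best <- function(X, y, A) {
  cv <- pls1_loocv(X, y, A)
  a <- which.min(cv$rmse)  # ties -> fewest components
  list(rmse = cv$rmse[a], n_lv = a, curve = cv$rmse)
}
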