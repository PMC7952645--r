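# Independent oracles used to verify the numerical operations. Each is a
# deliberately naive reimplementation (brute force, textbook formulas, or
# a different algorithm) kept free of the package's internal code paths.

# Savitzky-Golay: per-position least-squares polyfit over the (possibly
# edge-shrunken) window, evaluated at the position.
oracle_sg <- function(x, window = 5L, degree = 2L) {
  p <- length(x)
  h <- (window - 1L) %/% 2L
  out <- numeric(p)
  for (i in seq_len(p)) {
    cols <- max(1L, i - h):min(p, i + h)
    fit <- lm(y ~ poly(t, degree, raw = TRUE),
              data = data.frame(t = cols - i, y = x[cols]))
    out[i] <- unname(predict(fit, newdata = data.frame(t = 0)))
  }
  out
}

# Upper convex hull by exhaustive pair enumeration: the hull is the lower
# envelope of every point-pair line that dominates all points.
oracle_upper_hull <- function(x, y) {
  n <- length(x)
  env <- rep(Inf, n)
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      sl <- (y[k] - y[j]) / (x[k] - x[j])
      line <- y[j] + sl * (x - x[j])
      if (all(y <= line + 1e-12)) env <- pmin(env, line)
    }
  }
  env
}

# Reference PLS1 predictor that never forms regression coefficients:
# components by textbook NIPALS, prediction by sequentially deflating the
# new spectrum and accumulating q_m * t_m.
oracle_pls_fit <- function(X, y, a) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  W <- NULL; P <- NULL; q <- c()
  for (m in seq_len(a)) {
    w <- drop(crossprod(Xc, yc)); w <- w / sqrt(sum(w^2))
    t <- drop(Xc %*% w)
    pm <- drop(crossprod(Xc, t)) / sum(t^2)
    qm <- sum(t * yc) / sum(t^2)
    Xc <- Xc - outer(t, pm); yc <- yc - qm * t
    W <- cbind(W, w); P <- cbind(P, pm); q <- c(q, qm)
  }
  list(W = W, P = P, q = q, xm = xm, ym = ym)
}

oracle_pls_predict <- function(fit, xnew) {
  apply(rbind(xnew), 1, function(x) {
    xc <- x - fit$xm
    yhat <- fit$ym
    for (m in seq_along(fit$q)) {
      t <- sum(xc * fit$W[, m])
      yhat <- yhat + fit$q[m] * t
      xc <- xc - t * fit$P[, m]
    }
    yhat
  })
}

# B-coefficients of the reference model extracted by finite differences
# on the (linear) predictor, independent of any coefficient algebra.
oracle_pls_coefs <- function(fit) {
  p <- length(fit$xm)
  base <- oracle_pls_predict(fit, fit$xm)
  vapply(seq_len(p), function(j) {
    e <- fit$xm; e[j] <- e[j] + 1
    oracle_pls_predict(fit, e) - base
  }, numeric(1))
}

# Brute-force LOOCV RMSE curve using only the reference fit/predict.
oracle_loocv <- function(X, y, A) {
  n <- nrow(X)
  pred <- matrix(NA_real_, n, A)
  for (i in seq_len(n)) {
    for (a in seq_len(A)) {
      fit <- oracle_pls_fit(X[-i, , drop = FALSE], y[-i], a)
      pred[i, a] <- oracle_pls_predict(fit, X[i, ])
    }
  }
  sqrt(colMeans((pred - y)^2))
}

# Brute-force LOOCV RMSE of OLS with intercept (for the PRESS identity).
oracle_ols_loocv <- function(X, y) {
  n <- nrow(X)
  e <- vapply(seq_len(n), function(i) {
    fit <- lm(y[-i] ~ X[-i, , drop = FALSE])
    y[i] - sum(c(1, X[i, ]) * coef(fit))
  }, numeric(1))
  sqrt(mean(e^2))
}

# One bidirectional stepwise pass implemented with stats::add1/drop1.
oracle_stepwise <- function(X, y, p_enter = 0.01, p_remove = 0.05) {
  df <- as.data.frame(X)
  names(df) <- paste0("b", seq_len(ncol(X)))
  df$y <- y
  included <- character(0)
  trajectory <- list()
  repeat {
    changed <- FALSE
    fit <- lm(stats::reformulate(c("1", included), "y"), data = df)
    pool <- setdiff(names(df)[-ncol(df)], included)
    if (length(pool)) {
      a1 <- stats::add1(fit, scope = stats::reformulate(c(included, pool)),
                        test = "F")
      pv <- a1[["Pr(>F)"]][-1]
      j <- which.min(pv)
      if (length(j) && is.finite(pv[j]) && pv[j] < p_enter) {
        included <- c(included, rownames(a1)[-1][j])
        trajectory <- c(trajectory, list(c("add", rownames(a1)[-1][j])))
        changed <- TRUE
      }
    }
    repeat {
      if (!length(included)) break
      fit <- lm(stats::reformulate(c("1", included), "y"), data = df)
      d1 <- stats::drop1(fit, test = "F")
      pv <- d1[["Pr(>F)"]][-1]
      worst <- which(pv >= p_remove)
      if (!length(worst)) break
      w <- worst[which.max(pv[worst])]
      trajectory <- c(trajectory, list(c("remove", rownames(d1)[-1][w])))
      included <- setdiff(included, rownames(d1)[-1][w])
      changed <- TRUE
    }
    if (!changed) break
  }
  list(included = sort(as.integer(sub("b", "", included))),
       trajectory = trajectory)
}

# SPA projection chain built with lm() residuals: at each step every
# remaining column is regressed (no intercept) on the chosen columns and
# the one with the largest residual norm joins the chain.
oracle_spa_chain <- function(X, start, size) {
  chain <- start
  while (length(chain) < size) {
    rest <- setdiff(seq_len(ncol(X)), chain)
    norms <- vapply(rest, function(j) {
      r <- stats::residuals(lm(X[, j] ~ X[, chain, drop = FALSE] - 1))
      sum(r^2)
    }, numeric(1))
    chain <- c(chain, rest[which.max(norms)])
  }
  chain
}
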