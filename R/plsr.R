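#' Fit a PLS1 regression model
#'
#' Single-response partial least squares regression by NIPALS on
#' mean-centered (not variance-scaled) data. Weight vectors have unit
#' norm per latent variable (LV); the per-LV explained sum of squares of
#' the response is stored for VIP computation. With `n_lv` equal to the
#' rank of a full-column-rank tall predictor matrix, predictions coincide
#' with ordinary least squares.
#'
#' @param X Predictor matrix, samples x bands.
#' @param y Response vector (PWC, percent).
#' @param n_lv Number of latent variables, `1 <= n_lv <= min(n - 1, p)`.
#' @param wavelengths_nm Optional band wavelengths carried for reporting.
#' @return An object of class `plsr_model` with elements
#'   `weight_vectors` (p x M), `x_loadings`, `y_loadings`,
#'   `b_coefficients` (original centered-predictor scale), `intercept`,
#'   `x_mean`, `y_mean`, `explained_y_ss`, `n_lv` and `band_count`.
#' @export
fit_plsr <- function(X, y, n_lv, wavelengths_nm = NULL) {
  X <- assert_matrix_like(X, "X")
  y <- as.numeric(y)
  if (anyNA(y)) stopf("`y` must not contain missing values")
  if (length(y) != nrow(X)) stopf("`y` length must match nrow(X)")
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L || n_lv > min(nrow(X) - 1L, ncol(X)))
    stopf("`n_lv` must lie in [1, min(n - 1, p)] = [1, %d]",
          min(nrow(X) - 1L, ncol(X)))
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  if (var(y) < .Machine$double.eps) {
    # degenerate response: constant model
    fit <- list(W = matrix(0, ncol(X), 0), P = matrix(0, ncol(X), 0),
                q = numeric(0), ss = numeric(0), n_lv = 0L)
    b <- numeric(ncol(X))
  } else {
    fit <- pls1_engine(sweep(X, 2L, x_mean), y - y_mean, n_lv)
    if (fit$n_lv < n_lv)
      warning(sprintf("X deflated to zero after %d of %d requested LVs",
                      fit$n_lv, n_lv), call. = FALSE)
    b <- pls1_coef(fit)
  }
  structure(
    list(
      n_lv = fit$n_lv,
      weight_vectors = fit$W,
      x_loadings = fit$P,
      y_loadings = fit$q,
      b_coefficients = b,
      intercept = y_mean - sum(x_mean * b),
      x_mean = x_mean,
      y_mean = y_mean,
      explained_y_ss = fit$ss,
      band_count = ncol(X),
      wavelengths_nm = wavelengths_nm
    ),
    class = "plsr_model"
  )
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("plsr_model: %d latent variables over %d bands\n",
              x$n_lv, x$band_count))
  cat(sprintf("  intercept %.4g, mean response %.4g\n", x$intercept, x$y_mean))
  invisible(x)
}

#' @export
coef.plsr_model <- function(object, ...) object$b_coefficients

#' Predict PWC from a fitted PLS1 model
#'
#' `intercept + X_new %*% b`, i.e. `y_mean + (X_new - x_mean) %*% b`.
#'
#' @param object A `plsr_model`.
#' @param newdata Matrix with the model's band count, or a single
#'   spectrum vector.
#' @param ... Unused.
#' @return Predicted PWC vector.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- assert_matrix_like(newdata, "newdata")
  if (ncol(newdata) != object$band_count)
    stopf("newdata has %d bands but the model expects %d",
          ncol(newdata), object$band_count)
  drop(object$intercept + newdata %*% object$b_coefficients)
}

#' Leave-one-out cross-validation RMSE curve
#'
#' For each LV count `a = 1..A_max`, refits the model on every `n - 1`
#' subset (fresh centering each time) and predicts the held-out sample; the
#' curve entry is the RMSE of those `n` held-out predictions. The chosen
#' LV count is by default the global minimum of the curve (ties resolved
#' toward fewer LVs). `rule = "onese"` instead applies the
#' one-standard-error parsimony rule: the fewest LVs whose RMSE is within
#' one standard error of the minimum (a smoother criterion for curves
#' that flatten without a sharp minimum).
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param A_max Largest LV count to scan; default
#'   `min(20, n - 2, p)`.
#' @param rule LV choice rule, `"min"` (default) or `"onese"`.
#' @return An object of class `plsr_cv`: list with `rmse_cv` (length
#'   `A_max`), `chosen_lv`, `A_max` and `rule`.
#' @export
loocv_rmse_curve <- function(X, y, A_max = NULL, rule = c("min", "onese")) {
  X <- assert_matrix_like(X, "X")
  y <- as.numeric(y)
  rule <- match.arg(rule)
  n <- nrow(X)
  if (n < 3L) stopf("at least 3 samples are required")
  A_max <- as.integer(A_max %||% min(20L, n - 2L, ncol(X)))
  if (A_max < 1L) stopf("`A_max` must be >= 1")
  A_max <- min(A_max, n - 2L, ncol(X))
  cv <- pls1_loocv(X, y, A_max)
  chosen <- which.min(cv$rmse)
  if (rule == "onese") {
    err2 <- (cv$pred[, chosen] - y)^2
    se <- sd(err2) / sqrt(n) / (2 * cv$rmse[chosen])  # delta-method SE of RMSE
    chosen <- which(cv$rmse <= cv$rmse[which.min(cv$rmse)] + se)[1]
  }
  structure(
    list(rmse_cv = cv$rmse, chosen_lv = as.integer(chosen),
         A_max = A_max, rule = rule),
    class = "plsr_cv"
  )
}

#' @export
print.plsr_cv <- function(x, ...) {
  cat(sprintf("plsr_cv: RMSE_CV over 1..%d LVs, chosen %d (%.4g, rule %s)\n",
              x$A_max, x$chosen_lv, x$rmse_cv[x$chosen_lv], x$rule))
  invisible(x)
}

#' Variable importance in projection (VIP) scores
#'
#' `VIP_j = sqrt(p * sum_m(w_mj^2 SS_m) / sum_m(SS_m))`, where `p` is the
#' band count, `w_mj` the unit-norm loading weight of band `j` on LV `m`
#' and `SS_m` the explained sum of squares of the response by LV `m`.
#' The squared scores average to 1 (`sum(VIP^2) = p`), so the
#' conventional screening threshold is 1.
#'
#' @param model A fitted `plsr_model`.
#' @return Per-band VIP vector (all `>= 0`).
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsr_model"))
  if (model$n_lv == 0L || sum(model$explained_y_ss) <= 0)
    stopf("degenerate model: no explained response variance")
  W2 <- model$weight_vectors^2
  ss <- model$explained_y_ss
  sqrt(model$band_count * drop(W2 %*% ss) / sum(ss))
}

#' Serialize a fitted model to a structured text file
#'
#' Writes every model component (band grid, coefficients, intercept,
#' centering vectors, LV count, loadings) in R's exact hex-numeric text
#' representation, so [read_plsr_model()] restores a model whose
#' predictions are bit-identical.
#'
#' @param model A `plsr_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plsr_model <- function(model, path) {
  stopifnot(inherits(model, "plsr_model"))
  dput(unclass(model), file = path, control = c("all", "hexNumeric"))
  invisible(path)
}

#' @rdname write_plsr_model
#' @export
read_plsr_model <- function(path) {
  obj <- dget(path)
  class(obj) <- "plsr_model"
  obj
}
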