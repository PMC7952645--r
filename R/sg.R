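#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing along the band axis: at each
#' band the value of a degree-`degree` polynomial fitted to the
#' surrounding `window` bands, evaluated at the window midpoint. Near the
#' spectrum edges the window shrinks to the available one-sided bands
#' (the fit remains a least-squares polynomial of the same degree), so
#' the output has the same shape as the input. Assumes a uniform grid.
#'
#' With the default window 5 / degree 2 a constant or any exact quadratic
#' spectrum is reproduced.
#'
#' @param x Numeric matrix (samples x bands) or vector.
#' @param window Odd window width in bands (default 5).
#' @param degree Polynomial degree (default 2), must be `< window`.
#' @return Smoothed matrix (or vector) of the same shape.
#' @export
sg_smooth <- function(x, window = 5L, degree = 2L) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  x <- assert_matrix_like(x)
  window <- as.integer(window); degree <- as.integer(degree)
  if (window %% 2L != 1L) stopf("`window` must be odd")
  if (degree >= window) stopf("`degree` must be smaller than `window`")
  p <- ncol(x)
  if (window >= p + 1L) stopf("`window` (%d) must not exceed the band count (%d)", window, p)
  h <- (window - 1L) %/% 2L
  out <- matrix(0, nrow(x), p)
  # interior: fixed symmetric convolution weights
  offs <- -h:h
  wts <- sg_fit_row(offs, 0L, degree)
  interior <- (h + 1L):(p - h)
  acc <- matrix(0, nrow(x), length(interior))
  for (k in seq_along(offs))
    acc <- acc + wts[k] * x[, interior + offs[k], drop = FALSE]
  out[, interior] <- acc
  # edges: shrinking one-sided windows
  for (i in seq_len(h)) {
    cols <- 1L:min(i + h, p)
    w <- sg_fit_row(cols - i, 0L, degree)
    out[, i] <- x[, cols, drop = FALSE] %*% w
    j <- p - i + 1L
    cols <- max(1L, j - h):p
    w <- sg_fit_row(cols - j, 0L, degree)
    out[, j] <- x[, cols, drop = FALSE] %*% w
  }
  if (vec) drop(out) else out
}

# Least-squares polynomial evaluation weights: value at offset `at` of the
# degree-`degree` polynomial fitted to points at integer offsets `offs`.
#' @noRd
sg_fit_row <- function(offs, at, degree) {
  deg <- min(degree, length(offs) - 1L)
  V <- outer(offs, 0:deg, `^`)
  # row of the hat matrix for the evaluation point
  drop((outer(at, 0:deg, `^`) %*% solve(crossprod(V), t(V))))
}
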