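#' The nine spectral transformation identifiers
#'
#' @return Character vector of method ids: raw reflectance (`R`), the
#'   reciprocal (`recip`), log10 of the reciprocal (`log_recip`), first
#'   derivative (`d1`), first derivatives of the reciprocal and of the
#'   log-reciprocal (`d1_recip`, `d1_log_recip`), continuum removal
#'   (`CR`), multiplicative scatter correction (`MSC`) and per-sample
#'   peak normalization (`norm`).
#' @export
transform_methods <- function() {
  c("R", "recip", "log_recip", "d1", "d1_recip", "d1_log_recip",
    "CR", "MSC", "norm")
}

#' First derivative of spectra over a masked grid
#'
#' Central finite differences with respect to wavelength within each
#' contiguous segment of the mask; one-sided differences at segment
#' edges. Differences are never taken across an excluded gap. Output has
#' the same shape as the input; adding a constant to the spectra leaves
#' the derivative unchanged.
#'
#' @param values Matrix (samples x bands) on the masked grid.
#' @param wavelengths_nm Masked wavelength grid.
#' @param mask The [spectral_mask()] defining the segments.
#' @return Matrix of derivatives (reflectance units per nm).
#' @export
first_derivative <- function(values, wavelengths_nm, mask = spectral_mask()) {
  values <- assert_matrix_like(values)
  if (ncol(values) != length(wavelengths_nm))
    stopf("values/grid mismatch")
  seg_id <- mask_segment_id(wavelengths_nm, mask)
  if (anyNA(seg_id))
    stopf("grid contains bands outside the mask; apply the mask first")
  out <- matrix(0, nrow(values), ncol(values))
  for (s in unique(seg_id)) {
    idx <- which(seg_id == s)
    if (length(idx) < 3L)
      stopf("segment %d has fewer than 3 bands", s)
    wl <- wavelengths_nm[idx]
    v <- values[, idx, drop = FALSE]
    m <- length(idx)
    d <- matrix(0, nrow(v), m)
    d[, 2:(m - 1)] <- (v[, 3:m, drop = FALSE] - v[, 1:(m - 2), drop = FALSE]) /
      rep(wl[3:m] - wl[1:(m - 2)], each = nrow(v))
    d[, 1] <- (v[, 2] - v[, 1]) / (wl[2] - wl[1])
    d[, m] <- (v[, m] - v[, m - 1]) / (wl[m] - wl[m - 1])
    out[, idx] <- d
  }
  out
}

#' Continuum removal
#'
#' Divides each spectrum, per contiguous mask segment, by its upper
#' convex hull (piecewise linear, anchored at the segment endpoints).
#' Output lies in `(0, 1]`, with exact 1 at the hull touch points (at
#' least the two segment endpoints).
#'
#' @param values Matrix (samples x bands) of strictly positive values on
#'   the masked grid, or a single spectrum vector.
#' @param wavelengths_nm Masked wavelength grid.
#' @param mask The [spectral_mask()] defining the segments.
#' @return Continuum-removed matrix (or vector) in `(0, 1]`.
#' @export
continuum_removal <- function(values, wavelengths_nm, mask = spectral_mask()) {
  vec <- is.null(dim(values))
  if (vec) values <- matrix(values, nrow = 1L)
  values <- assert_matrix_like(values)
  if (any(values <= 0)) stopf("continuum removal requires strictly positive values")
  seg_id <- mask_segment_id(wavelengths_nm, mask)
  if (anyNA(seg_id)) stopf("grid contains bands outside the mask; apply the mask first")
  out <- matrix(0, nrow(values), ncol(values))
  for (s in unique(seg_id)) {
    idx <- which(seg_id == s)
    wl <- wavelengths_nm[idx]
    for (i in seq_len(nrow(values))) {
      v <- values[i, idx]
      hull <- upper_hull_continuum(wl, v)
      out[i, idx] <- v / hull
    }
  }
  out <- pmin(out, 1)  # guard FP overshoot at touch points
  if (vec) drop(out) else out
}

# Piecewise-linear upper convex hull through (x, y), evaluated at x.
# Monotone-chain over points sorted in x; keeps only upper-hull vertices.
#' @noRd
upper_hull_continuum <- function(x, y) {
  n <- length(x)
  h <- integer(n); k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L) {
      # drop h[k] if it lies on or below the chord h[k-1] -> i
      cr <- (x[h[k]] - x[h[k - 1L]]) * (y[i] - y[h[k - 1L]]) -
        (y[h[k]] - y[h[k - 1L]]) * (x[i] - x[h[k - 1L]])
      if (cr >= 0) k <- k - 1L else break
    }
    k <- k + 1L
    h[k] <- i
  }
  hull_idx <- h[seq_len(k)]
  stats::approx(x[hull_idx], y[hull_idx], xout = x, method = "linear")$y
}

#' Multiplicative scatter correction
#'
#' Per sample, regress the spectrum on a reference spectrum
#' (`x_i = a_i * reference + b_i + e`) by ordinary least squares over the
#' retained bands and return `(x_i - b_i) / a_i`. The reference must come
#' from the calibration set (its per-band mean); validation spectra are
#' corrected against the calibration reference.
#'
#' @param values Matrix (samples x bands).
#' @param reference Per-band reference spectrum; defaults to
#'   `colMeans(values)` (calibration use).
#' @return Corrected matrix with the reference attached as attribute
#'   `"reference"`.
#' @export
msc_correct <- function(values, reference = NULL) {
  values <- assert_matrix_like(values)
  reference <- reference %||% colMeans(values)
  if (length(reference) != ncol(values))
    stopf("`reference` must have one value per band")
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  if (denom < 1e-24) stopf("degenerate (constant) reference spectrum")
  a <- as.vector(values %*% rc) / denom  # per-sample slope
  b <- rowMeans(values) - a * mean(reference)
  if (any(abs(a) < 1e-12)) stopf("degenerate sample: MSC slope ~ 0")
  out <- (values - b) / a
  attr(out, "reference") <- reference
  out
}

#' Per-sample peak normalization
#'
#' Divides each spectrum by its own maximum over the retained bands, so
#' every normalized spectrum peaks at exactly 1 while the curve shape
#' (band rank order) is preserved.
#'
#' @param values Matrix (samples x bands).
#' @return Normalized matrix.
#' @export
normalize_peak <- function(values) {
  values <- assert_matrix_like(values)
  mx <- apply(values, 1L, max)
  if (any(mx <= 0)) stopf("per-sample maximum must be positive")
  values / mx
}

#' Apply one of the nine spectral transformations
#'
#' Input is expected to be smoothed and masked already (the pipeline
#' order is fixed: smooth, then trim/mask, then transform). Reflectance
#' is floored at `1e-6` before the reciprocal and logarithmic transforms.
#' The log is base 10 (absorbance convention).
#'
#' @param values Matrix (samples x bands) on the masked grid.
#' @param method_id One of [transform_methods()].
#' @param wavelengths_nm Masked wavelength grid.
#' @param mask The [spectral_mask()] used (needed by the derivative and
#'   continuum-removal transforms for segment boundaries).
#' @param reference Optional MSC reference spectrum (required when
#'   transforming validation data; calibration data default to their own
#'   mean).
#' @return An object of class `transformed_spectra`: list with
#'   `method_id`, `wavelengths_nm`, `values` and (for MSC) the reference.
#' @export
apply_transform <- function(values, method_id, wavelengths_nm,
                            mask = spectral_mask(), reference = NULL) {
  values <- assert_matrix_like(values)
  method_id <- match.arg(method_id, transform_methods())
  pos <- function(v) pmax(v, 1e-6)
  ref_out <- NULL
  out <- switch(
    method_id,
    R = values,
    recip = 1 / pos(values),
    log_recip = log10(1 / pos(values)),
    d1 = first_derivative(values, wavelengths_nm, mask),
    d1_recip = first_derivative(1 / pos(values), wavelengths_nm, mask),
    d1_log_recip = first_derivative(log10(1 / pos(values)), wavelengths_nm, mask),
    CR = continuum_removal(pos(values), wavelengths_nm, mask),
    MSC = {
      v <- msc_correct(values, reference)
      ref_out <- attr(v, "reference")
      attr(v, "reference") <- NULL
      v
    },
    norm = normalize_peak(values)
  )
  structure(
    list(
      method_id = method_id,
      wavelengths_nm = wavelengths_nm,
      values = out,
      reference = ref_out
    ),
    class = "transformed_spectra"
  )
}

#' @export
print.transformed_spectra <- function(x, ...) {
  cat(sprintf("transformed_spectra [%s]: %d samples x %d bands\n",
              x$method_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Smooth, mask and transform a spectra set
#'
#' The fixed preprocessing order of the workflow: Savitzky-Golay
#' smoothing on the full grid, trimming/masking, then one of the nine
#' transformations. With `method_id = "R"` the result is the masked
#' smoothed spectra unchanged.
#'
#' @param x A [spectra_set()].
#' @param method_id One of [transform_methods()].
#' @param mask A [spectral_mask()].
#' @param window,degree Savitzky-Golay parameters (defaults 5 and 2).
#' @param reference MSC reference from the calibration set, if
#'   transforming validation data.
#' @return A `transformed_spectra` object; the sample PWC vector travels
#'   along as element `pwc`.
#' @export
preprocess_spectra <- function(x, method_id = "R", mask = spectral_mask(),
                               window = 5L, degree = 2L, reference = NULL) {
  stopifnot(inherits(x, "spectra_set"))
  sm <- sg_smooth(x$reflectance, window = window, degree = degree)
  keep <- mask_keep(x$wavelengths_nm, mask)
  wl <- x$wavelengths_nm[keep]
  tr <- apply_transform(sm[, keep, drop = FALSE], method_id, wl,
                        mask = mask, reference = reference)
  tr$pwc <- x$pwc
  tr$metadata <- x$metadata
  tr
}

#' Write transformed spectra to a wide CSV with a metadata sidecar
#'
#' The values go to `path` in the same wide dialect as
#' [write_spectra_csv()] (metadata, `pwc`, one column per wavelength);
#' the transform provenance (`method_id`, band count) goes to a JSON
#' sidecar at `<path>.json`.
#'
#' @param x A `transformed_spectra` object carrying `pwc`/`metadata`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_transformed_csv <- function(x, path) {
  stopifnot(inherits(x, "transformed_spectra"))
  if (is.null(x$pwc)) stopf("transformed spectra lack the sample PWC vector")
  ss <- spectra_set(x$wavelengths_nm, x$values, x$pwc,
                    x$metadata %||% data.frame(row = seq_along(x$pwc)))
  write_spectra_csv(ss, path)
  jsonlite::write_json(
    list(method_id = x$method_id, band_count = length(x$wavelengths_nm)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write a band-wise correlation curve as a two-column CSV
#'
#' @param x Output of [correlation_with_target()].
#' @param path CSV path (`wavelength_nm`, `r`).
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(x, path) {
  data.table::fwrite(x[, c("wavelength_nm", "r")], path)
  invisible(path)
}

#' Band-wise Pearson correlation with the response
#'
#' @param transformed A `transformed_spectra` object (or plain matrix).
#' @param pwc Response vector (defaults to the PWC carried by the
#'   transformed object).
#' @return Data frame with `wavelength_nm`, `r` and `zero_variance`
#'   (bands with zero variance get `r = 0` and a flag).
#' @export
correlation_with_target <- function(transformed, pwc = NULL) {
  if (inherits(transformed, "transformed_spectra")) {
    values <- transformed$values
    wl <- transformed$wavelengths_nm
    pwc <- pwc %||% transformed$pwc
  } else {
    values <- assert_matrix_like(transformed)
    wl <- attr(transformed, "wavelengths_nm") %||% seq_len(ncol(values))
  }
  if (is.null(pwc)) stopf("`pwc` is required")
  if (length(pwc) != nrow(values)) stopf("`pwc` length must match sample count")
  if (nrow(values) < 3L) stopf("at least 3 samples are required")
  yc <- pwc - mean(pwc)
  vc <- sweep(values, 2L, colMeans(values))
  num <- as.vector(crossprod(vc, yc))
  vss <- colSums(vc^2)
  yss <- sum(yc^2)
  if (yss == 0) stopf("response has zero variance")
  zero_var <- vss < .Machine$double.eps * nrow(values)
  r <- numeric(length(num))
  r[!zero_var] <- num[!zero_var] / sqrt(vss[!zero_var] * yss)
  r <- pmin(pmax(r, -1), 1)
  data.frame(wavelength_nm = wl, r = r, zero_variance = zero_var)
}
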