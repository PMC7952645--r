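#' Spectral trimming and water-vapor mask
#'
#' The working range is trimmed to 400-2450 nm and the atmospheric
#' water-vapor windows around 1400 nm (1350-1400 nm) and 1900 nm
#' (1800-1950 nm) are removed. All intervals are closed: a band equal to
#' an interval endpoint is excluded. On a 1-nm integer grid this leaves
#' 1849 retained bands in three contiguous segments.
#'
#' @param retained_range Closed `[min, max]` retained interval, nm.
#' @param excluded_intervals List of closed intervals (length-2 vectors)
#'   removed from the retained range.
#' @return An object of class `spectral_mask` with the derived
#'   `contiguous_segments` (ordered, disjoint intervals covering the
#'   retained range minus the exclusions).
#' @export
spectral_mask <- function(retained_range = c(400, 2450),
                          excluded_intervals = list(c(1350, 1400), c(1800, 1950))) {
  if (length(retained_range) != 2L || diff(retained_range) <= 0)
    stopf("`retained_range` must be an increasing interval")
  excluded_intervals <- lapply(excluded_intervals, function(iv) {
    if (length(iv) != 2L || diff(iv) < 0) stopf("excluded intervals must be [lo, hi]")
    if (iv[1] < retained_range[1] || iv[2] > retained_range[2])
      stopf("excluded intervals must lie inside the retained range")
    as.numeric(iv)
  })
  if (length(excluded_intervals) > 1L) {
    o <- order(vapply(excluded_intervals, `[`, numeric(1), 1L))
    excluded_intervals <- excluded_intervals[o]
    lo <- vapply(excluded_intervals, `[`, numeric(1), 1L)
    hi <- vapply(excluded_intervals, `[`, numeric(1), 2L)
    if (any(lo[-1] <= hi[-length(hi)])) stopf("excluded intervals must be disjoint")
  }
  # derived open segments between exclusions
  segs <- list()
  cur <- retained_range[1]
  for (iv in excluded_intervals) {
    if (iv[1] > cur) segs <- c(segs, list(c(cur, iv[1])))
    cur <- iv[2]
  }
  if (cur < retained_range[2]) segs <- c(segs, list(c(cur, retained_range[2])))
  structure(
    list(
      retained_range = as.numeric(retained_range),
      excluded_intervals = excluded_intervals,
      contiguous_segments = segs
    ),
    class = "spectral_mask"
  )
}

#' @export
print.spectral_mask <- function(x, ...) {
  cat(sprintf("spectral_mask: retain [%g, %g] nm\n",
              x$retained_range[1], x$retained_range[2]))
  for (iv in x$excluded_intervals)
    cat(sprintf("  exclude [%g, %g] nm\n", iv[1], iv[2]))
  invisible(x)
}

# Logical keep-vector for a wavelength grid under a mask. Bands equal to
# an excluded-interval endpoint are dropped (closed intervals).
#' @noRd
mask_keep <- function(wavelengths_nm, mask) {
  keep <- wavelengths_nm >= mask$retained_range[1] &
    wavelengths_nm <= mask$retained_range[2]
  for (iv in mask$excluded_intervals)
    keep <- keep & !(wavelengths_nm >= iv[1] & wavelengths_nm <= iv[2])
  keep
}

# Segment id (1-based, NA for masked bands) for each retained wavelength.
#' @noRd
mask_segment_id <- function(wavelengths_nm, mask) {
  id <- rep(NA_integer_, length(wavelengths_nm))
  for (s in seq_along(mask$contiguous_segments)) {
    seg <- mask$contiguous_segments[[s]]
    inseg <- wavelengths_nm >= seg[1] & wavelengths_nm <= seg[2] &
      mask_keep(wavelengths_nm, mask)
    id[inseg] <- s
  }
  id
}

#' Apply a spectral mask to a spectra set
#'
#' Drops all bands outside the retained range and inside the excluded
#' closed intervals; band order is preserved.
#'
#' @param x A [spectra_set()] (or a plain matrix, in which case
#'   `wavelengths_nm` must be supplied).
#' @param mask A [spectral_mask()].
#' @param wavelengths_nm Grid for matrix input.
#' @return Masked object of the same kind; for matrix input, a matrix
#'   with a `wavelengths_nm` attribute.
#' @export
apply_mask <- function(x, mask = spectral_mask(), wavelengths_nm = NULL) {
  if (inherits(x, "spectra_set")) {
    wl <- x$wavelengths_nm
    if (min(wl) > mask$retained_range[1] || max(wl) < mask$retained_range[2])
      stopf("spectra grid [%g, %g] does not cover the retained range [%g, %g]",
            min(wl), max(wl), mask$retained_range[1], mask$retained_range[2])
    keep <- mask_keep(wl, mask)
    return(spectra_set(wl[keep], x$reflectance[, keep, drop = FALSE],
                       x$pwc, x$metadata))
  }
  x <- assert_matrix_like(x)
  if (is.null(wavelengths_nm)) stopf("`wavelengths_nm` required for matrix input")
  if (min(wavelengths_nm) > mask$retained_range[1] ||
      max(wavelengths_nm) < mask$retained_range[2])
    stopf("grid does not cover the retained range")
  keep <- mask_keep(wavelengths_nm, mask)
  out <- x[, keep, drop = FALSE]
  attr(out, "wavelengths_nm") <- wavelengths_nm[keep]
  out
}
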