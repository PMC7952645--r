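#' Spectra + PWC container
#'
#' Couples a wavelength grid, a samples x bands reflectance (or
#' transformed-spectra) matrix, the PWC response vector and per-sample
#' metadata. All downstream operations take and return this container or
#' plain matrices extracted from it.
#'
#' @param wavelengths_nm Strictly increasing wavelength grid, nm.
#' @param reflectance Numeric matrix, samples x bands, no missing values.
#' @param pwc PWC vector, percent, one value per sample.
#' @param metadata Data frame with one row per sample (season, cultivar,
#'   treatment, replicate, date).
#'
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(wavelengths_nm, reflectance, pwc, metadata) {
  reflectance <- assert_matrix_like(reflectance, "reflectance")
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (any(diff(wavelengths_nm) <= 0))
    stopf("`wavelengths_nm` must be strictly increasing")
  if (ncol(reflectance) != length(wavelengths_nm))
    stopf("reflectance has %d columns but the grid has %d wavelengths",
          ncol(reflectance), length(wavelengths_nm))
  pwc <- as.numeric(pwc)
  if (anyNA(pwc)) stopf("`pwc` must not contain missing values")
  if (nrow(reflectance) != length(pwc))
    stopf("reflectance has %d rows but `pwc` has length %d",
          nrow(reflectance), length(pwc))
  if (!is.data.frame(metadata) || nrow(metadata) != length(pwc))
    stopf("`metadata` must be a data frame with one row per sample")
  dimnames(reflectance) <- NULL
  structure(
    list(
      wavelengths_nm = wavelengths_nm,
      reflectance = reflectance,
      pwc = pwc,
      metadata = metadata
    ),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d samples x %d bands (%g-%g nm)\n",
              nrow(x$reflectance), ncol(x$reflectance),
              min(x$wavelengths_nm), max(x$wavelengths_nm)))
  cat(sprintf("  PWC: %.1f-%.1f%% (median %.1f%%)\n",
              min(x$pwc), max(x$pwc), stats::median(x$pwc)))
  if (nrow(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$reflectance)

#' Write a spectra set to a wide CSV file
#'
#' Dialect: first column `sample_id`, then the metadata columns
#' (`season,cultivar,treatment,replicate,date`), then `pwc`, then one
#' column per wavelength named by its nm value. Values are written with
#' full precision so that [read_spectra_csv()] round-trips losslessly.
#'
#' @param x A [spectra_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "spectra_set"))
  refl <- data.table::as.data.table(x$reflectance)
  data.table::setnames(refl, as.character(x$wavelengths_nm))
  out <- data.table::data.table(sample_id = seq_len(nrow(x$reflectance)))
  for (nm in names(x$metadata)) out[[nm]] <- x$metadata[[nm]]
  out[["pwc"]] <- x$pwc
  out <- cbind(out, refl)
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read a spectra set written by [write_spectra_csv()]
#'
#' @param path CSV path.
#' @return A [spectra_set()].
#' @export
read_spectra_csv <- function(path) {
  dt <- data.table::fread(path)
  nm <- names(dt)
  wl_cols <- nm[!is.na(suppressWarnings(as.numeric(nm)))]
  if (!length(wl_cols)) stopf("no wavelength columns found in %s", path)
  if (!"pwc" %in% nm) stopf("no `pwc` column found in %s", path)
  meta_cols <- setdiff(nm, c("sample_id", "pwc", wl_cols))
  spectra_set(
    wavelengths_nm = as.numeric(wl_cols),
    reflectance = as.matrix(dt[, wl_cols, with = FALSE]),
    pwc = dt[["pwc"]],
    metadata = as.data.frame(dt[, meta_cols, with = FALSE])
  )
}
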