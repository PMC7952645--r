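# internal helpers

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr under a fixed RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("`seed` must be a single finite integer")
  withr::with_seed(as.integer(seed), expr)
}

#' @noRd
assert_matrix_like <- function(x, what = "spectra") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stopf("`%s` must be a numeric matrix (samples x bands)", what)
  if (anyNA(x)) stopf("`%s` must not contain missing values", what)
  x
}

# tie-break helper: first index of the minimum (ties -> earliest position)
#' @noRd
which_min_first <- function(x) which.min(x)
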