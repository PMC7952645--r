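#' Evaluate predictions: R2, RMSE and RPIQ
#'
#' `R2 = 1 - SSE/SST`; `RMSE = sqrt(mean((pred - obs)^2))` with the
#' evaluated dataset's own size in the denominator; `RPIQ = (Q3 - Q1) /
#' RMSE` where the quartiles of the observed response use the common
#' linear-interpolation convention (`stats::quantile` type 7, logged in
#' the report). A perfect fit gives RMSE 0 and a flagged infinite RPIQ.
#'
#' @param observed Observed PWC vector (percent), length >= 4, non-zero
#'   variance.
#' @param predicted Predicted PWC vector of the same length.
#' @param role `"calibration"` or `"validation"`.
#' @param model_id,n_lv,band_count Optional provenance carried into the
#'   report.
#' @return An object of class `evaluation_report`.
#' @export
evaluate_predictions <- function(observed, predicted,
                                 role = c("calibration", "validation"),
                                 model_id = NA_character_,
                                 n_lv = NA_integer_,
                                 band_count = NA_integer_) {
  role <- match.arg(role)
  observed <- as.numeric(observed)
  predicted <- as.numeric(predicted)
  if (length(observed) != length(predicted))
    stopf("`observed` and `predicted` must have equal length")
  if (length(observed) < 4L) stopf("at least 4 samples are required")
  if (anyNA(observed) || anyNA(predicted)) stopf("missing values in inputs")
  sst <- sum((observed - mean(observed))^2)
  if (sst <= 0) stopf("observed values have zero variance")
  n <- length(observed)
  rmse <- sqrt(sum((predicted - observed)^2) / n)
  r2 <- 1 - sum((observed - predicted)^2) / sst
  q <- quantile(observed, c(0.25, 0.75), type = 7, names = FALSE)
  rpiq_flagged <- rmse == 0
  rpiq <- if (rpiq_flagged) Inf else (q[2] - q[1]) / rmse
  structure(
    list(dataset_role = role, n = n, r2 = r2, rmse = rmse, rpiq = rpiq,
         rpiq_infinite = rpiq_flagged,
         category = rpiq_category(rpiq),
         quartiles = q, quartile_type = 7L,
         model_id = model_id, n_lv = n_lv, band_count = band_count),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation [%s%s] n=%d: R2 %.3f, RMSE %.2f%%, RPIQ %s (%s)\n",
              if (is.na(x$model_id)) "" else paste0(x$model_id, ", "),
              x$dataset_role, x$n, x$r2, x$rmse,
              if (is.finite(x$rpiq)) sprintf("%.2f", x$rpiq) else "Inf",
              x$category))
  invisible(x)
}

#' RPIQ model-quality category
#'
#' Thresholds: RPIQ in `[2.02, 2.70)` — poor (only high and low values
#' distinguishable); `[2.70, 3.37)` — quantitative predictions possible;
#' `[3.37, 4.05]` — good quantitative model; above 4.05 — excellent.
#' Values below 2.02 are flagged `below-poor`.
#'
#' @param rpiq Positive RPIQ value (vectorized).
#' @return Character category.
#' @export
rpiq_category <- function(rpiq) {
  if (any(rpiq[is.finite(rpiq)] <= 0)) stopf("RPIQ must be positive")
  out <- character(length(rpiq))
  out[rpiq < 2.02] <- "below-poor"
  out[rpiq >= 2.02 & rpiq < 2.70] <- "poor"
  out[rpiq >= 2.70 & rpiq < 3.37] <- "quantitative"
  out[rpiq >= 3.37 & rpiq <= 4.05] <- "good"
  out[rpiq > 4.05] <- "excellent"
  out
}

#' Ranked comparison table of evaluated models
#'
#' One row per model with LV/band provenance and the calibration and
#' validation metric blocks, sorted by validation RPIQ in decreasing
#' order (models lacking a validation report sort by calibration RPIQ;
#' equal RPIQ keeps the input order).
#'
#' @param reports A list; each element is either a single
#'   `evaluation_report` or a list with elements `calibration` and
#'   `validation`.
#' @return A data frame.
#' @export
comparison_table <- function(reports) {
  if (!length(reports)) stopf("at least one report is required")
  if (inherits(reports, "evaluation_report")) reports <- list(reports)
  rows <- lapply(reports, function(rep) {
    if (inherits(rep, "evaluation_report"))
      rep <- if (rep$dataset_role == "calibration") list(calibration = rep)
             else list(validation = rep)
    cal <- rep$calibration
    val <- rep$validation
    prov <- cal %||% val
    data.frame(
      model_id = prov$model_id,
      n_lv = prov$n_lv,
      band_count = prov$band_count,
      r2_cal = if (is.null(cal)) NA_real_ else cal$r2,
      rmse_cal = if (is.null(cal)) NA_real_ else cal$rmse,
      rpiq_cal = if (is.null(cal)) NA_real_ else cal$rpiq,
      category_cal = if (is.null(cal)) NA_character_ else cal$category,
      r2_val = if (is.null(val)) NA_real_ else val$r2,
      rmse_val = if (is.null(val)) NA_real_ else val$rmse,
      rpiq_val = if (is.null(val)) NA_real_ else val$rpiq,
      category_val = if (is.null(val)) NA_character_ else val$category,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  key <- ifelse(is.na(tab$rpiq_val), tab$rpiq_cal, tab$rpiq_val)
  tab <- tab[order(-key, seq_len(nrow(tab))), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
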