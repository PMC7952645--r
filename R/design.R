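#' Experimental design of a field season
#'
#' Describes one growing season of the irrigation trial: two cultivars,
#' five irrigation treatments, three replicate plots and four or five
#' sampling dates, i.e. one plot-level record per cultivar x treatment x
#' replicate x date.
#'
#' @param season_label Free-text label, e.g. `"2014-2015"`.
#' @param cultivars Character vector of length 2.
#' @param treatments Data frame with columns `label`, `irrigation_level`
#'   (fraction of field capacity in `[0, 1]`, strictly decreasing) and
#'   `field_capacity_percent`. See [treatment_spec()].
#' @param replicates Number of replicate plots per treatment (default 3).
#' @param sampling_dates Character vector of date labels (5 for season one,
#'   4 for season two).
#'
#' @return An object of class `pwc_design`.
#' @seealso [design_season_one()], [design_season_two()]
#' @export
experiment_design <- function(season_label, cultivars, treatments,
                              replicates = 3L, sampling_dates) {
  if (length(cultivars) != 2L) stopf("`cultivars` must have length 2")
  if (!is.data.frame(treatments) || nrow(treatments) != 5L)
    stopf("`treatments` must be a data frame with 5 rows")
  need <- c("label", "irrigation_level", "field_capacity_percent")
  if (!all(need %in% names(treatments)))
    stopf("`treatments` must have columns %s", paste(need, collapse = ", "))
  lv <- treatments$irrigation_level
  if (any(!is.finite(lv)) || any(lv < 0) || any(lv > 1))
    stopf("irrigation levels must lie in [0, 1]")
  if (any(diff(lv) >= 0))
    stopf("irrigation levels must be strictly decreasing from the wettest to the driest treatment")
  replicates <- as.integer(replicates)
  if (replicates < 1L) stopf("`replicates` must be >= 1")
  if (length(sampling_dates) < 1L) stopf("at least one sampling date is required")
  structure(
    list(
      season_label = as.character(season_label),
      cultivars = as.character(cultivars),
      treatments = treatments,
      replicates = replicates,
      sampling_dates = as.character(sampling_dates)
    ),
    class = "pwc_design"
  )
}

#' Irrigation treatment specification
#'
#' @param label Treatment label (`"W1"` ... `"W5"` or `"I1"` ... `"I5"`).
#' @param irrigation_level Effective fraction of field capacity in `[0, 1]`.
#' @param field_capacity_percent Field capacity of the trial soil; the
#'   default 24.14 is the value measured for the Calcareous Cinnamon soil
#'   of the trial site.
#' @param n_irrigations Optional count of irrigation events (season-two
#'   treatments are defined by event timing rather than an upper limit).
#'
#' @return A one-row data frame.
#' @export
treatment_spec <- function(label, irrigation_level,
                           field_capacity_percent = 24.14,
                           n_irrigations = NA_integer_) {
  data.frame(
    label = as.character(label),
    irrigation_level = as.numeric(irrigation_level),
    field_capacity_percent = as.numeric(field_capacity_percent),
    n_irrigations = as.integer(n_irrigations),
    stringsAsFactors = FALSE
  )
}

#' Season one (2014-2015) design: irrigation upper limits W1..W5
#'
#' Five upper limits of irrigation for each 10-day period (80, 60, 45, 35
#' and under 30 percent of field capacity), two cultivars, three replicate
#' plots and five sampling dates, giving 150 plot-level records.
#'
#' @return A `pwc_design`.
#' @export
design_season_one <- function() {
  tr <- do.call(rbind, list(
    treatment_spec("W1", 0.80),
    treatment_spec("W2", 0.60),
    treatment_spec("W3", 0.45),
    treatment_spec("W4", 0.35),
    treatment_spec("W5", 0.28)
  ))
  experiment_design(
    season_label = "2014-2015",
    cultivars = c("Jinnong 190", "Chang 4738"),
    treatments = tr,
    replicates = 3L,
    sampling_dates = c("2015-04-13", "2015-04-24", "2015-05-03",
                       "2015-05-13", "2015-05-22")
  )
}

#' Season two (2015-2016) design: irrigation frequencies I1..I5
#'
#' Treatments defined by the number and timing of irrigation events
#' (four, three, two, two and zero irrigations; upper limit 80 percent of
#' field capacity). The `irrigation_level` column maps each regime to an
#' effective season-average fraction of field capacity so that treatments
#' are strictly ordered from wettest to driest (I3, two irrigations placed
#' at jointing and flowering, is scored slightly wetter than I4 whose
#' second irrigation only arrives at filling). Four sampling dates give
#' 120 plot-level records.
#'
#' @return A `pwc_design`.
#' @export
design_season_two <- function() {
  tr <- do.call(rbind, list(
    treatment_spec("I1", 0.80, n_irrigations = 4L),
    treatment_spec("I2", 0.65, n_irrigations = 3L),
    treatment_spec("I3", 0.50, n_irrigations = 2L),
    treatment_spec("I4", 0.42, n_irrigations = 2L),
    treatment_spec("I5", 0.25, n_irrigations = 0L)
  ))
  experiment_design(
    season_label = "2015-2016",
    cultivars = c("Chang 4738", "Zhongmai 175"),
    treatments = tr,
    replicates = 3L,
    sampling_dates = c("2016-04-13", "2016-04-22", "2016-05-13",
                       "2016-05-21")
  )
}

#' Number of plot-level records implied by a design
#'
#' cultivars x treatments x replicates x dates.
#'
#' @param design A `pwc_design`.
#' @return Integer record count (150 for season one, 120 for season two).
#' @export
design_record_count <- function(design) {
  stopifnot(inherits(design, "pwc_design"))
  length(design$cultivars) * nrow(design$treatments) *
    design$replicates * length(design$sampling_dates)
}

#' @export
print.pwc_design <- function(x, ...) {
  cat("Experimental design:", x$season_label, "\n")
  cat("  cultivars:  ", paste(x$cultivars, collapse = ", "), "\n")
  cat("  treatments: ", paste(x$treatments$label, collapse = ", "), "\n")
  cat("  replicates: ", x$replicates, "\n")
  cat("  dates:      ", paste(x$sampling_dates, collapse = ", "), "\n")
  cat("  records:    ", design_record_count(x), "\n")
  invisible(x)
}

#' Plant water content from fresh and dry weight
#'
#' PWC (percent, dry-weight basis) = (FW - DW) / DW x 100. Because the
#' denominator is the dry weight, values above 100 percent are normal for
#' well-watered wheat.
#'
#' @param fresh_weight_g,dry_weight_g Sample weights in grams.
#' @return PWC in percent.
#' @export
pwc_from_weights <- function(fresh_weight_g, dry_weight_g) {
  if (any(dry_weight_g <= 0)) stopf("dry weight must be positive")
  if (any(fresh_weight_g < dry_weight_g))
    stopf("fresh weight must be >= dry weight")
  (fresh_weight_g - dry_weight_g) / dry_weight_g * 100
}
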