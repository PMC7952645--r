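#' Default configuration for the end-to-end study
#'
#' One nested list drives the whole pipeline: experimental designs,
#' scene parameters, mask, smoothing, the transform list, PLSR settings
#' and per-method selection parameters. Every stochastic stage draws its
#' seed deterministically from the single global `seed` (calibration
#' data: `seed`; validation data: `seed + 2`; random frog: `seed + 4`;
#' UVE noise block: `seed + 5`).
#'
#' @param seed Global integer seed.
#' @param output_dir Output directory for [run_all()] (default: a fresh
#'   temporary directory).
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(seed = 42L, output_dir = NULL) {
  structure(
    list(
      seed = as.integer(seed),
      output_dir = output_dir,
      design = list(calibration = "season_one", validation = "season_two"),
      scene = list(),
      mask = list(retained = c(400, 2450),
                  excluded = list(c(1350, 1400), c(1800, 1950))),
      smoothing = list(window = 5L, degree = 2L),
      transforms = transform_methods(),
      plsr = list(a_max = 20L, lv_rule = "min"),
      selection = list(base_transform = "d1",
                       spa_max_size = 30L,
                       sr_p_enter = 0.01, sr_p_remove = 0.05,
                       rf_iterations = 1000L, rf_patience = 30L,
                       rf_inner_lv = 5L,
                       uve_noise_scale = 1e-10)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Missing keys fall back to [default_run_config()]; unknown keys are
#' rejected with the offending path in the error.
#'
#' @param path YAML file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  validate_run_config(user)
  base <- default_run_config()
  cfg <- utils::modifyList(base, user)
  # modifyList drops the class and can't replace list-valued leaves wholesale
  if (!is.null(user$transforms)) cfg$transforms <- unlist(user$transforms)
  if (!is.null(user$mask$excluded)) cfg$mask$excluded <- user$mask$excluded
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

#' @noRd
validate_run_config <- function(cfg) {
  known <- list(
    top = c("seed", "output_dir", "design", "scene", "mask", "smoothing",
            "transforms", "plsr", "selection"),
    design = c("calibration", "validation"),
    mask = c("retained", "excluded"),
    smoothing = c("window", "degree"),
    plsr = c("a_max", "lv_rule"),
    selection = c("base_transform", "spa_max_size", "sr_p_enter",
                  "sr_p_remove", "rf_iterations", "rf_patience",
                  "rf_inner_lv", "uve_noise_scale")
  )
  check <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stopf("unknown configuration key%s under `%s`: %s",
            if (length(bad) > 1) "s" else "", where,
            paste(bad, collapse = ", "))
  }
  check(cfg, known$top, "config")
  for (sec in c("design", "mask", "smoothing", "plsr", "selection"))
    if (!is.null(cfg[[sec]])) check(cfg[[sec]], known[[sec]], sec)
  if (!is.null(cfg$scene)) {
    allowed <- names(formals(scene_params))
    check(cfg$scene, setdiff(allowed, "..."), "scene")
  }
  if (!is.null(cfg$transforms)) {
    bad <- setdiff(unlist(cfg$transforms), transform_methods())
    if (length(bad)) stopf("unknown transform id: %s", paste(bad, collapse = ", "))
  }
  invisible(cfg)
}

#' @noRd
config_design <- function(id) {
  switch(id,
         season_one = design_season_one(),
         season_two = design_season_two(),
         stopf("unknown design preset `%s` (use season_one or season_two)", id))
}

#' @noRd
config_scene <- function(cfg) do.call(scene_params, cfg$scene %||% list())

#' @noRd
config_mask <- function(cfg) {
  spectral_mask(retained_range = unlist(cfg$mask$retained),
                excluded_intervals = lapply(cfg$mask$excluded, unlist))
}

# Generate the calibration/validation datasets of a configuration.
#' @noRd
config_datasets <- function(cfg) {
  scene <- config_scene(cfg)
  list(
    calibration = generate_dataset(config_design(cfg$design$calibration),
                                   scene, seed = cfg$seed),
    validation = generate_dataset(config_design(cfg$design$validation),
                                  scene, seed = cfg$seed + 2L),
    scene = scene
  )
}

#' Compare PLSR models over the configured spectral transforms
#'
#' The calibration season is used to fit one PLSR model per transform
#' (LV count by leave-one-out cross-validation); the validation season
#' is transformed with calibration-derived parameters only (the MSC
#' reference is the calibration mean spectrum; prediction uses
#' calibration centering) and never enters model fitting. Emits a ranked
#' comparison table with one row per transform.
#'
#' @param config A `run_config`.
#' @param datasets Optional precomputed output of the internal dataset
#'   generator (used by [run_all()] to avoid re-simulation).
#' @return List with `table` (data frame), `models`, `cv_curves`,
#'   `reports`, `transformed` and `datasets`.
#' @export
run_transform_comparison <- function(config = default_run_config(),
                                     datasets = NULL) {
  validate_run_config(config)
  ds <- datasets %||% config_datasets(config)
  mask <- config_mask(config)
  win <- config$smoothing$window
  deg <- config$smoothing$degree
  models <- list(); cvs <- list(); reports <- list(); transformed <- list()
  for (m in config$transforms) {
    cal <- preprocess_spectra(ds$calibration, m, mask, win, deg)
    val <- preprocess_spectra(ds$validation, m, mask, win, deg,
                              reference = cal$reference)
    cv <- loocv_rmse_curve(cal$values, cal$pwc, A_max = config$plsr$a_max,
                           rule = config$plsr$lv_rule)
    fit <- fit_plsr(cal$values, cal$pwc, cv$chosen_lv,
                    wavelengths_nm = cal$wavelengths_nm)
    rep_c <- evaluate_predictions(cal$pwc, predict(fit, cal$values),
                                  "calibration", model_id = m,
                                  n_lv = fit$n_lv, band_count = fit$band_count)
    rep_v <- evaluate_predictions(val$pwc, predict(fit, val$values),
                                  "validation", model_id = m,
                                  n_lv = fit$n_lv, band_count = fit$band_count)
    models[[m]] <- fit; cvs[[m]] <- cv
    reports[[m]] <- list(calibration = rep_c, validation = rep_v)
    transformed[[m]] <- list(calibration = cal, validation = val)
  }
  list(table = comparison_table(reports), models = models, cv_curves = cvs,
       reports = reports, transformed = transformed, datasets = ds)
}

#' Screen and refine sensitive bands, then refit and evaluate
#'
#' Runs the B+VIP screen on the base-transform model (first derivative
#' by default, the transform the full-spectrum comparison favours), then
#' the four combined selectors (stepwise regression, successive
#' projections, random frog, uninformative variable elimination) on the
#' screened candidate matrix. Each band set gets a fresh PLSR fit (LV by
#' LOOCV) evaluated on both seasons, yielding a five-row table.
#'
#' @param config A `run_config`.
#' @param base_transform Transform the selection operates on.
#' @param context Optional output of [run_transform_comparison()]; when
#'   absent, the base-transform model is recomputed.
#' @return List with `table`, `selections`, `models`, `reports` and the
#'   screened candidate wavelengths.
#' @export
run_band_selection <- function(config = default_run_config(),
                               base_transform = NULL, context = NULL) {
  validate_run_config(config)
  base_transform <- base_transform %||% config$selection$base_transform
  if (!is.null(context) && base_transform %in% names(context$models)) {
    base_model <- context$models[[base_transform]]
    cal <- context$transformed[[base_transform]]$calibration
    val <- context$transformed[[base_transform]]$validation
  } else {
    ds <- if (!is.null(context)) context$datasets else config_datasets(config)
    mask <- config_mask(config)
    cal <- preprocess_spectra(ds$calibration, base_transform, mask,
                              config$smoothing$window, config$smoothing$degree)
    val <- preprocess_spectra(ds$validation, base_transform, mask,
                              config$smoothing$window, config$smoothing$degree,
                              reference = cal$reference)
    cv <- loocv_rmse_curve(cal$values, cal$pwc, A_max = config$plsr$a_max,
                           rule = config$plsr$lv_rule)
    base_model <- fit_plsr(cal$values, cal$pwc, cv$chosen_lv,
                           wavelengths_nm = cal$wavelengths_nm)
  }
  screen <- screen_b_vip(base_model)
  if (!length(screen$selected_idx))
    stopf("band selection: the B+VIP screen selected no bands")
  base_reports <- list(
    calibration = evaluate_predictions(cal$pwc, predict(base_model, cal$values),
                                       "calibration", model_id = base_transform,
                                       n_lv = base_model$n_lv,
                                       band_count = base_model$band_count),
    validation = evaluate_predictions(val$pwc, predict(base_model, val$values),
                                      "validation", model_id = base_transform,
                                      n_lv = base_model$n_lv,
                                      band_count = base_model$band_count)
  )
  sc <- config$selection
  Xc <- cal$values[, screen$selected_idx, drop = FALSE]
  wlc <- screen$selected_bands
  y <- cal$pwc
  selections <- list(BVIP = screen)
  selections$BVIP_SR <- stepwise_select(Xc, y, wlc,
                                        p_enter = sc$sr_p_enter,
                                        p_remove = sc$sr_p_remove)
  selections$BVIP_SPA <- spa_select(Xc, y, wlc, max_size = sc$spa_max_size)
  selections$BVIP_RF <- random_frog_select(Xc, y, wlc,
                                           n_iterations = sc$rf_iterations,
                                           seed = config$seed + 4L,
                                           init_size = base_model$n_lv,
                                           n_lv_inner = sc$rf_inner_lv,
                                           patience = sc$rf_patience)
  selections$BVIP_UVE <- uve_select(Xc, y, wlc, seed = config$seed + 5L,
                                    noise_scale = sc$uve_noise_scale,
                                    n_lv = base_model$n_lv)
  models <- list(); reports <- list()
  for (m in names(selections)) {
    idx_full <- match(selections[[m]]$selected_bands, cal$wavelengths_nm)
    if (!length(idx_full)) {
      warning(sprintf("%s selected no bands; skipping refit", m), call. = FALSE)
      next
    }
    Xm <- cal$values[, idx_full, drop = FALSE]
    Vm <- val$values[, idx_full, drop = FALSE]
    cv <- loocv_rmse_curve(Xm, y, A_max = min(config$plsr$a_max, ncol(Xm)),
                           rule = config$plsr$lv_rule)
    fit <- fit_plsr(Xm, y, cv$chosen_lv,
                    wavelengths_nm = cal$wavelengths_nm[idx_full])
    models[[m]] <- fit
    reports[[m]] <- list(
      calibration = evaluate_predictions(y, predict(fit, Xm), "calibration",
                                         model_id = m, n_lv = fit$n_lv,
                                         band_count = ncol(Xm)),
      validation = evaluate_predictions(val$pwc, predict(fit, Vm), "validation",
                                        model_id = m, n_lv = fit$n_lv,
                                        band_count = ncol(Xm))
    )
  }
  list(table = comparison_table(reports), selections = selections,
       models = models, reports = reports,
       base_transform = base_transform, base_model = base_model,
       base_reports = base_reports, screen_wavelengths = wlc)
}

#' Run the complete study and write the report bundle
#'
#' Simulate both seasons, compare the nine transforms, select bands on
#' the base transform, refit and evaluate, and write everything under
#' `config$output_dir`: the two comparison tables, per-model 1:1
#' scatter data (observed vs predicted, both roles), per-method selected
#' band lists with diagnostics sidecars, and a reproducibility manifest
#' (package version, seeds, configuration, config hash). Rerunning with
#' the same configuration reproduces the outputs byte for byte.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with `transform_comparison`,
#'   `band_selection`, `manifest` and `output_dir`.
#' @export
run_all <- function(config = default_run_config()) {
  validate_run_config(config)
  out_dir <- config$output_dir %||% file.path(tempdir(), "pwcspec-run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tc <- run_transform_comparison(config)
  bs <- run_band_selection(config, context = tc)
  fwrite_num <- function(x, f)
    data.table::fwrite(x, file.path(out_dir, f))
  fwrite_num(tc$table, "transform_comparison.csv")
  fwrite_num(bs$table, "band_selection.csv")
  scatter <- function(reports, transformed, models, tag) {
    for (m in names(models)) {
      fit <- models[[m]]
      for (role in c("calibration", "validation")) {
        td <- transformed[[role]]
        X <- if (tag == "selection")
          td$values[, match(fit$wavelengths_nm, td$wavelengths_nm), drop = FALSE]
        else td$values
        fwrite_num(data.frame(observed = td$pwc, predicted = predict(fit, X)),
                   sprintf("scatter_%s_%s_%s.csv", tag, m, role))
      }
    }
  }
  for (m in names(tc$models))
    scatter(tc$reports[m], tc$transformed[[m]], tc$models[m], "transform")
  sel_td <- tc$transformed[[bs$base_transform]] %||% {
    # base transform outside the configured transform list: rebuild
    mask <- config_mask(config)
    list(calibration = preprocess_spectra(tc$datasets$calibration,
                                          bs$base_transform, mask),
         validation = preprocess_spectra(tc$datasets$validation,
                                         bs$base_transform, mask))
  }
  scatter(bs$reports, sel_td, bs$models, "selection")
  for (m in names(bs$selections))
    write_selection_result(bs$selections[[m]],
                           file.path(out_dir, sprintf("bands_%s.csv", m)))
  cfg_path <- file.path(out_dir, "config.yaml")
  cfg_record <- unclass(config)
  cfg_record$output_dir <- NULL  # hash the science, not the destination
  yaml::write_yaml(cfg_record, cfg_path)
  manifest <- list(
    package = "pwcspec",
    version = as.character(packageVersion("pwcspec")),
    seed = config$seed,
    derived_seeds = list(calibration_data = config$seed,
                         validation_data = config$seed + 2L,
                         random_frog = config$seed + 4L,
                         uve_noise = config$seed + 5L),
    config_hash = unname(tools::md5sum(cfg_path)),
    tables = c("transform_comparison.csv", "band_selection.csv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(transform_comparison = tc, band_selection = bs,
                 manifest = manifest, output_dir = out_dir))
}
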