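# Shared fixtures, built in code.

# Small random regression problem with planted linear signal.
tiny_problem <- function(n = 12, p = 6, seed = 1, informative = 1:2,
                         noise = 0.1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    beta <- numeric(p)
    beta[informative] <- seq_along(informative)
    list(X = X, y = drop(X %*% beta + rnorm(n, sd = noise)), beta = beta)
  })
}

# A coarse-grid configuration that keeps pipeline tests fast: 5 nm grid,
# three transforms, modest LV scan, light random frog.
fast_config <- function(seed = 11L, output_dir = NULL) {
  cfg <- default_run_config(seed = seed, output_dir = output_dir)
  cfg$scene <- list(wavelength_step = 5)
  cfg$transforms <- c("R", "d1", "MSC")
  cfg$plsr$a_max <- 8L
  cfg$selection$rf_iterations <- 120L
  cfg$selection$spa_max_size <- 15L
  cfg
}

# Memoised full-scale selection runs shared by the selection-property and
# acceptance tests: the complete screen + four selectors on the default
# synthetic calibration season, for seeds 1..5.
acceptance_runs <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    runs <- lapply(1:5, function(seed) {
      cfg <- default_run_config(seed = seed)
      bs <- run_band_selection(cfg)
      screen_n <- length(bs$selections$BVIP$selected_bands)
      methods <- c("BVIP_SR", "BVIP_SPA", "BVIP_RF", "BVIP_UVE")
      reduction <- vapply(methods, function(m)
        100 * (1 - length(bs$selections[[m]]$selected_bands) / screen_n),
        numeric(1))
      registry <- scene_params()$informative_band_registry
      coverage <- vapply(c("BVIP_SR", "BVIP_RF"), function(m) {
        sel <- bs$selections[[m]]$selected_bands
        mean(vapply(registry, function(w) any(abs(sel - w) <= 10), logical(1)))
      }, numeric(1))
      r2_cal <- vapply(bs$reports, function(r) r$calibration$r2, numeric(1))
      list(seed = seed, screen_n = screen_n, selections = bs$selections,
           reduction = reduction, coverage = coverage, r2_cal = r2_cal,
           r2_cal_full = bs$base_reports$calibration$r2)
    })
    cache <<- runs
    runs
  }
})
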