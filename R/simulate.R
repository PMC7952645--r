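#' Simulate plant water content for a field design
#'
#' PWC (percent, dry-weight basis) declines linearly across sampling dates
#' from a treatment-dependent start to a treatment-dependent end, plus a
#' small cultivar offset and Gaussian plot noise. Wetter treatments start
#' and end higher, so at every date the treatment means are ordered with
#' irrigation, and every cultivar x replicate trajectory declines over the
#' season — the qualitative structure observed in the field trial.
#'
#' Trajectory defaults: the wettest treatment runs from about 400 percent
#' at the first date to 150 percent at the last; each step down the
#' irrigation ladder lowers the start by 18 and the end by 26 percent, so
#' simulated values span roughly 50-400 percent.
#'
#' @param design A [experiment_design()] object.
#' @param seed Integer seed; output is reproducible given the seed.
#' @param start_max,start_step Start-of-season PWC of the wettest treatment
#'   and per-treatment-rank decrement, percent.
#' @param end_max,end_step Same for the final date.
#' @param cultivar_offset Offset (percent) applied as +x to the first
#'   cultivar and -x to the second.
#' @param noise_sd Plot-level Gaussian noise, percent.
#'
#' @return A data frame with one row per plot-level record: `season`,
#'   `cultivar`, `treatment`, `replicate`, `date`, `date_index`,
#'   `irrigation_level` and `pwc`.
#' @export
simulate_pwc <- function(design, seed,
                         start_max = 400, start_step = 18,
                         end_max = 150, end_step = 26,
                         cultivar_offset = 4, noise_sd = 6) {
  if (!inherits(design, "pwc_design")) stopf("`design` must be a `pwc_design`")
  n_dates <- length(design$sampling_dates)
  if (n_dates < 1L || nrow(design$treatments) < 1L || length(design$cultivars) < 1L)
    stopf("empty design")
  grid <- expand.grid(
    date_index = seq_len(n_dates),
    replicate = seq_len(design$replicates),
    treatment = design$treatments$label,
    cultivar = design$cultivars,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[, c("cultivar", "treatment", "replicate", "date_index")]
  grid <- grid[order(match(grid$cultivar, design$cultivars),
                     match(grid$treatment, design$treatments$label),
                     grid$replicate, grid$date_index), , drop = FALSE]
  rownames(grid) <- NULL
  rank <- match(grid$treatment, design$treatments$label)  # 1 = wettest
  frac <- if (n_dates > 1L) (grid$date_index - 1) / (n_dates - 1) else rep(0, nrow(grid))
  start <- start_max - start_step * (rank - 1)
  end <- end_max - end_step * (rank - 1)
  cult <- ifelse(grid$cultivar == design$cultivars[1], cultivar_offset, -cultivar_offset)
  mean_pwc <- start + (end - start) * frac + cult
  pwc <- with_seed(seed, mean_pwc + rnorm(nrow(grid), sd = noise_sd))
  data.frame(
    season = design$season_label,
    cultivar = grid$cultivar,
    treatment = grid$treatment,
    replicate = grid$replicate,
    date = design$sampling_dates[grid$date_index],
    date_index = grid$date_index,
    irrigation_level = design$treatments$irrigation_level[rank],
    pwc = pmax(pwc, 5),
    stringsAsFactors = FALSE
  )
}

#' Simulate a single canopy reflectance spectrum
#'
#' Adds the stochastic layers (per-feature depth jitter, per-sample
#' scatter, instrument noise) on top of the deterministic
#' [canopy_reflectance()] core. With all noise parameters zero the output
#' equals the noise-free core, in which case reflectance at every water
#' band center strictly decreases as PWC increases.
#'
#' @param pwc PWC in percent (scalar, must be positive).
#' @param treatment A one-row treatment data frame ([treatment_spec()]);
#'   its `irrigation_level` sets the expected soil fraction.
#' @param scene A [scene_params()] object.
#' @param seed Integer seed.
#' @return Reflectance vector over the scene grid, clipped to `(1e-4, 1)`.
#' @export
simulate_reflectance <- function(pwc, treatment, scene = scene_params(), seed = 1L) {
  if (length(pwc) != 1L || !is.finite(pwc) || pwc <= 0)
    stopf("`pwc` must be a single positive value (percent)")
  lev <- treatment$irrigation_level[1]
  with_seed(seed, {
    drop(simulate_reflectance_matrix(
      pwc = pwc, irrigation_level = lev, scene = scene
    ))
  })
}

# Vectorized stochastic scene model. Assumes the RNG state is already set
# by the caller. pwc and irrigation_level are parallel vectors.
#' @noRd
simulate_reflectance_matrix <- function(pwc, irrigation_level, scene) {
  n <- length(pwc)
  wl <- scene$wavelengths_nm
  p <- length(wl)
  # expected soil fraction decreases linearly with irrigation level
  fr <- scene$soil_fraction_range
  lev <- irrigation_level
  lev_lo <- min(lev); lev_hi <- max(lev)
  rel <- if (lev_hi > lev_lo) (lev - lev_lo) / (lev_hi - lev_lo) else rep(0.5, n)
  soil_frac <- fr[2] - (fr[2] - fr[1]) * rel
  soil_frac <- pmin(pmax(soil_frac + rnorm(n, sd = scene$soil_fraction_sd), 0), 1)
  nw <- length(scene$water_band_centers)
  nc <- length(scene$chlorophyll_centers)
  jit <- scene$feature_depth_jitter_sd
  refl <- matrix(0, n, p)
  ka <- scene$arch_n_components
  for (i in seq_len(n)) {
    s <- scene_saturations(pwc[i], scene)
    wm <- s$water * exp(rnorm(nw, sd = jit))
    cm <- s$chl * exp(rnorm(nc, sd = jit))
    km <- s$cont * exp(rnorm(1L, sd = jit))
    veg <- scene$baseline_spectrum -
      scene_absorption_profile(scene, water_mult = wm, chl_mult = cm,
                               cont_mult = km)
    refl[i, ] <- (1 - soil_frac[i]) * veg + soil_frac[i] * scene$soil_spectrum
    if (ka > 0L && scene$arch_amplitude_sd > 0) {
      # smooth canopy-architecture deformations, unrelated to PWC
      ac <- runif(ka, min(wl), max(wl))
      aw <- runif(ka, scene$arch_width_range[1], scene$arch_width_range[2])
      aa <- rnorm(ka, sd = scene$arch_amplitude_sd)
      for (k in seq_len(ka))
        refl[i, ] <- refl[i, ] + aa[k] * exp(-((wl - ac[k]) / aw[k])^2 / 2)
    }
  }
  a <- 1 + rnorm(n, sd = scene$scatter_mult_sd)
  b <- rnorm(n, sd = scene$scatter_add_sd)
  refl <- refl * a + b
  if (scene$noise_sd > 0)
    refl <- refl + matrix(rnorm(n * p, sd = scene$noise_sd), n, p)
  refl <- pmin(pmax(refl, 1e-4), 1)
  attr(refl, "soil_fraction") <- soil_frac
  refl
}

#' Generate a full synthetic spectra + PWC dataset
#'
#' One averaged plot-level record per cultivar x treatment x replicate x
#' date: 150 records for the season-one design, 120 for season two, each
#' with a reflectance spectrum on the scene grid (2151 bands for the
#' default 350-2500 nm at 1 nm) and a PWC value. Bit-identical output for
#' identical `(design, scene, seed)`.
#'
#' @param design A [experiment_design()] object.
#' @param scene A [scene_params()] object.
#' @param seed Integer seed controlling both the PWC draw and the
#'   reflectance noise.
#' @param ... Passed to [simulate_pwc()] (trajectory parameters).
#' @return A [spectra_set()].
#' @export
generate_dataset <- function(design, scene = scene_params(), seed, ...) {
  records <- simulate_pwc(design, seed = seed, ...)
  refl <- with_seed(seed + 1L, {
    simulate_reflectance_matrix(
      pwc = records$pwc,
      irrigation_level = records$irrigation_level,
      scene = scene
    )
  })
  meta <- records[, c("season", "cultivar", "treatment", "replicate", "date")]
  spectra_set(
    wavelengths_nm = scene$wavelengths_nm,
    reflectance = refl,
    pwc = records$pwc,
    metadata = meta
  )
}
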