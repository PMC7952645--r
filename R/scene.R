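#' Synthetic canopy scene parameters
#'
#' Parameters of the generative model used by [simulate_reflectance()] and
#' [generate_dataset()]. A noise-free canopy spectrum is a smooth baseline
#' (dark visible, red edge, bright NIR plateau, declining SWIR) minus
#' water-absorption features, chlorophyll valleys and a slowly rising
#' liquid-water continuum, all scaled by a saturating function of PWC,
#' then mixed linearly with a soil endmember whose fraction grows as
#' irrigation decreases. Per-sample multiplicative/additive scatter and
#' white instrument noise are added on top.
#'
#' Each water feature is the sum of a narrow Gaussian core (sharply
#' localized, so selection methods can be judged against the planted
#' positions) and a broad shallow base (so that absorption is felt between
#' feature centers, as in real canopies). Per-feature log-normal depth
#' jitter (`feature_depth_jitter_sd`) makes the features informationally
#' distinct rather than copies of one latent factor.
#'
#' @param water_band_centers Water absorption centers, nm.
#' @param water_band_widths Gaussian sigma of the narrow cores, nm.
#' @param water_depth_gain Reflectance depth of each core at full
#'   saturation; the 1750 nm feature is kept shallower than the dominant
#'   bands.
#' @param water_base_widths,water_base_gain Sigma and depth of the broad
#'   companion bases.
#' @param water_continuum_gain Depth at 2500 nm of the square-root liquid
#'   water continuum that rises from 800 nm.
#' @param chlorophyll_centers,chlorophyll_widths,chlorophyll_gain
#'   Chlorophyll absorption valleys in the visible (500 and 680 nm).
#' @param pwc_reference Per-water-feature saturation scale `p0` (percent):
#'   feature depth is `gain * (1 - exp(-pwc / p0))`, monotone increasing in
#'   PWC. Strong absorption bands (1450, 1950 nm) saturate at lower water
#'   content than weak ones (1750 nm), so the PWC information carried by
#'   the features is genuinely multivariate and PLSR models need several
#'   latent variables, as with real canopy spectra. A scalar is recycled.
#' @param chlorophyll_pwc_reference,continuum_pwc_reference Saturation
#'   scales of the chlorophyll valleys and the liquid-water continuum.
#' @param feature_depth_jitter_sd Standard deviation of the per-sample,
#'   per-feature log-normal depth jitter.
#' @param arch_n_components,arch_amplitude_sd,arch_width_range Structured
#'   interference emulating canopy-architecture and illumination-geometry
#'   variation: each sample receives the sum of `arch_n_components` broad
#'   Gaussian deformations with random centers over the grid, widths
#'   uniform in `arch_width_range` (nm) and amplitudes
#'   `N(0, arch_amplitude_sd)`. This PWC-unrelated structure is what
#'   forces multi-LV PLSR models, as in real canopy spectra.
#' @param soil_fraction_range Range `(min, max)` of the soil cover
#'   fraction; the fraction decreases linearly with irrigation level.
#' @param soil_fraction_sd Plot-to-plot noise on the soil fraction.
#' @param noise_sd Instrument (white) noise, reflectance units.
#' @param scatter_mult_sd,scatter_add_sd Per-sample multiplicative and
#'   additive scatter (what MSC is designed to remove).
#' @param wavelength_range,wavelength_step Spectral grid in nm; the default
#'   350-2500 nm at 1 nm yields 2151 bands.
#' @param baseline_spectrum Optional per-wavelength baseline reflectance in
#'   `(0, 1)`; defaults to [canopy_baseline()] on the grid.
#' @param soil_spectrum Optional soil endmember; defaults to
#'   [soil_endmember()].
#' @param informative_band_registry Wavelengths (nm) at which the scene
#'   plants PWC information; selection methods are expected to recover
#'   bands near these positions. 1950 nm is absent because the water-vapor
#'   mask removes it.
#'
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(water_band_centers = c(970, 1200, 1450, 1750, 1950, 2250),
                         water_band_widths = c(6, 6, 6, 6, 8, 6),
                         water_depth_gain = c(0.22, 0.18, 0.22, 0.15, 0.17, 0.18),
                         water_base_widths = c(80, 55, 60, 60, 70, 55),
                         water_base_gain = c(0.040, 0.025, 0.030, 0.024, 0.035, 0.028),
                         water_continuum_gain = 0.07,
                         chlorophyll_centers = c(500, 680),
                         chlorophyll_widths = c(7, 7),
                         chlorophyll_gain = c(0.12, 0.13),
                         pwc_reference = c(130, 170, 100, 260, 100, 150),
                         chlorophyll_pwc_reference = 260,
                         continuum_pwc_reference = 160,
                         feature_depth_jitter_sd = 0.16,
                         arch_n_components = 6L,
                         arch_amplitude_sd = 0.012,
                         arch_width_range = c(80, 300),
                         soil_fraction_range = c(0.08, 0.18),
                         soil_fraction_sd = 0.02,
                         noise_sd = 0.003,
                         scatter_mult_sd = 0.015,
                         scatter_add_sd = 0.004,
                         wavelength_range = c(350, 2500),
                         wavelength_step = 1,
                         baseline_spectrum = NULL,
                         soil_spectrum = NULL,
                         informative_band_registry = c(970, 1200, 1450, 1750, 2250)) {
  k <- length(water_band_centers)
  if (length(water_band_widths) != k || length(water_depth_gain) != k ||
      length(water_base_widths) != k || length(water_base_gain) != k)
    stopf("water feature parameter vectors must share the length of `water_band_centers`")
  if (length(chlorophyll_widths) != length(chlorophyll_centers) ||
      length(chlorophyll_gain) != length(chlorophyll_centers))
    stopf("chlorophyll parameter vectors must share the length of `chlorophyll_centers`")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  if (length(soil_fraction_range) != 2L || any(soil_fraction_range < 0) ||
      any(soil_fraction_range > 1) || diff(soil_fraction_range) < 0)
    stopf("`soil_fraction_range` must be an increasing interval inside [0, 1]")
  wl <- seq(wavelength_range[1], wavelength_range[2], by = wavelength_step)
  baseline <- baseline_spectrum %||% canopy_baseline(wl)
  soil <- soil_spectrum %||% soil_endmember(wl)
  if (length(baseline) != length(wl) || length(soil) != length(wl))
    stopf("baseline and soil spectra must match the wavelength grid (%d bands)", length(wl))
  if (any(baseline <= 0) || any(baseline >= 1))
    stopf("baseline reflectance must lie in (0, 1)")
  structure(
    list(
      water_band_centers = water_band_centers,
      water_band_widths = water_band_widths,
      water_depth_gain = water_depth_gain,
      water_base_widths = water_base_widths,
      water_base_gain = water_base_gain,
      water_continuum_gain = water_continuum_gain,
      chlorophyll_centers = chlorophyll_centers,
      chlorophyll_widths = chlorophyll_widths,
      chlorophyll_gain = chlorophyll_gain,
      pwc_reference = rep_len(pwc_reference, k),
      chlorophyll_pwc_reference = chlorophyll_pwc_reference,
      continuum_pwc_reference = continuum_pwc_reference,
      feature_depth_jitter_sd = feature_depth_jitter_sd,
      arch_n_components = as.integer(arch_n_components),
      arch_amplitude_sd = arch_amplitude_sd,
      arch_width_range = arch_width_range,
      soil_fraction_range = soil_fraction_range,
      soil_fraction_sd = soil_fraction_sd,
      noise_sd = noise_sd,
      scatter_mult_sd = scatter_mult_sd,
      scatter_add_sd = scatter_add_sd,
      wavelengths_nm = wl,
      baseline_spectrum = baseline,
      soil_spectrum = soil,
      informative_band_registry = informative_band_registry
    ),
    class = "scene_params"
  )
}

#' Smooth green-canopy baseline reflectance
#'
#' Dark visible with a green bump at 550 nm, a logistic red edge near
#' 720 nm, a NIR plateau of about 0.46 and a linear decline across the
#' SWIR. Absorption features are *not* part of the baseline; they are
#' subtracted from it according to PWC.
#'
#' @param wavelengths_nm Wavelength grid, nm.
#' @return Reflectance in `(0, 1)`, one value per wavelength.
#' @export
canopy_baseline <- function(wavelengths_nm) {
  wl <- wavelengths_nm
  vis <- 0.18 + 0.05 * exp(-((wl - 550) / 35)^2 / 2)
  nir <- 0.46 - 0.16 * pmax(0, wl - 1300) / 1200
  edge <- 1 / (1 + exp(-(wl - 715) / 12))
  vis * (1 - edge) + nir * edge
}

#' Soil endmember spectrum
#'
#' A featureless, monotonically brightening soil spectrum (about 0.18 in
#' the visible rising to 0.42 in the far SWIR), typical of a dry bright
#' calcareous soil: darker than the canopy NIR plateau but brighter than
#' the water-absorbing canopy across the SWIR.
#'
#' @param wavelengths_nm Wavelength grid, nm.
#' @return Reflectance per wavelength.
#' @export
soil_endmember <- function(wavelengths_nm) {
  0.18 + 0.24 * (wavelengths_nm - 350) / 2150
}

#' @export
print.scene_params <- function(x, ...) {
  cat("Synthetic canopy scene\n")
  cat(sprintf("  grid: %g-%g nm (%d bands)\n", min(x$wavelengths_nm),
              max(x$wavelengths_nm), length(x$wavelengths_nm)))
  cat("  water features (nm):", paste(x$water_band_centers, collapse = ", "), "\n")
  cat("  chlorophyll valleys (nm):", paste(x$chlorophyll_centers, collapse = ", "), "\n")
  cat("  registry (nm):", paste(x$informative_band_registry, collapse = ", "), "\n")
  cat(sprintf("  noise sd: %g, scatter (mult/add): %g/%g\n",
              x$noise_sd, x$scatter_mult_sd, x$scatter_add_sd))
  invisible(x)
}

# Total planted absorption profile at full saturation, optionally with
# per-feature depth multipliers (water cores+bases, chlorophyll, liquid
# water continuum). Returns a bands-long vector.
#' @noRd
scene_absorption_profile <- function(scene, water_mult = NULL, chl_mult = NULL,
                                     cont_mult = 1) {
  wl <- scene$wavelengths_nm
  k <- length(scene$water_band_centers)
  water_mult <- water_mult %||% rep(1, k)
  chl_mult <- chl_mult %||% rep(1, length(scene$chlorophyll_centers))
  prof <- numeric(length(wl))
  for (i in seq_len(k)) {
    c0 <- scene$water_band_centers[i]
    prof <- prof + water_mult[i] *
      (scene$water_depth_gain[i] * exp(-((wl - c0) / scene$water_band_widths[i])^2 / 2) +
         scene$water_base_gain[i] * exp(-((wl - c0) / scene$water_base_widths[i])^2 / 2))
  }
  for (i in seq_along(scene$chlorophyll_centers)) {
    c0 <- scene$chlorophyll_centers[i]
    prof <- prof + chl_mult[i] * scene$chlorophyll_gain[i] *
      exp(-((wl - c0) / scene$chlorophyll_widths[i])^2 / 2)
  }
  prof + cont_mult * scene$water_continuum_gain * sqrt(pmax(0, wl - 800) / 1700)
}

# Saturating depth response in PWC (percent): 1 - exp(-pwc/p0).
#' @noRd
pwc_saturation <- function(pwc, p0) 1 - exp(-pwc / p0)

# Per-channel saturation multipliers for one PWC value: water features,
# chlorophyll valleys and the continuum each follow their own scale.
#' @noRd
scene_saturations <- function(pwc, scene) {
  list(
    water = pwc_saturation(pwc, scene$pwc_reference),
    chl = rep_len(pwc_saturation(pwc, scene$chlorophyll_pwc_reference),
                  length(scene$chlorophyll_centers)),
    cont = pwc_saturation(pwc, scene$continuum_pwc_reference)
  )
}

#' Noise-free canopy reflectance for a given PWC and soil fraction
#'
#' The deterministic core of the scene model: baseline minus the planted
#' absorption profile scaled by the PWC saturation, mixed with the soil
#' endmember, clipped to `(1e-4, 1)`.
#'
#' @param pwc PWC in percent (scalar, positive).
#' @param soil_fraction Soil cover fraction in `[0, 1]`.
#' @param scene A [scene_params()] object.
#' @return Reflectance vector over the scene grid.
#' @export
canopy_reflectance <- function(pwc, soil_fraction, scene = scene_params()) {
  if (length(pwc) != 1L || !is.finite(pwc) || pwc <= 0)
    stopf("`pwc` must be a single positive value (percent)")
  if (soil_fraction < 0 || soil_fraction > 1)
    stopf("`soil_fraction` must lie in [0, 1]")
  s <- scene_saturations(pwc, scene)
  veg <- scene$baseline_spectrum -
    scene_absorption_profile(scene, water_mult = s$water, chl_mult = s$chl,
                             cont_mult = s$cont)
  r <- (1 - soil_fraction) * veg + soil_fraction * scene$soil_spectrum
  pmin(pmax(r, 1e-4), 1)
}
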