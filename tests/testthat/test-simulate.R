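# Uses a coarse 10 nm grid where full spectral resolution is not needed.
coarse_scene <- scene_params(wavelength_step = 10)

test_that("PWC simulation is seeded, sized and structured like the trial", {
  d1 <- design_season_one()
  pw <- simulate_pwc(d1, seed = 7)
  expect_equal(nrow(pw), 150)
  expect_identical(pw, simulate_pwc(d1, seed = 7))
  expect_false(identical(pw$pwc, simulate_pwc(d1, seed = 8)$pwc))
  expect_equal(nrow(simulate_pwc(design_season_two(), seed = 7)), 120)
  # dry-weight-basis values span roughly 50-400%
  expect_gt(max(pw$pwc), 300)
  expect_lt(min(pw$pwc), 100)
  expect_true(all(pw$pwc > 0))
})

test_that("mean PWC declines over dates and increases with irrigation", {
  for (design in list(design_season_one(), design_season_two())) {
    for (seed in 1:5) {
      pw <- simulate_pwc(design, seed = seed)
      # per cultivar x replicate trajectory of date means is non-increasing
      cell_means <- aggregate(pwc ~ cultivar + replicate + date_index, pw, mean)
      for (cu in unique(cell_means$cultivar)) {
        for (rp in unique(cell_means$replicate)) {
          tr <- cell_means[cell_means$cultivar == cu & cell_means$replicate == rp, ]
          expect_true(all(diff(tr$pwc[order(tr$date_index)]) < 0))
        }
      }
      # at each date, treatment means ordered with irrigation level
      dm <- aggregate(pwc ~ treatment + date_index, pw, mean)
      lv <- design$treatments$irrigation_level[
        match(dm$treatment, design$treatments$label)]
      for (dt in unique(dm$date_index)) {
        sub <- dm[dm$date_index == dt, ]
        o <- order(lv[dm$date_index == dt])  # driest first
        expect_true(all(diff(sub$pwc[o]) > 0))
      }
    }
  }
})

test_that("wettest beats driest at the final date, averaged over seeds", {
  d1 <- design_season_one()
  final <- length(d1$sampling_dates)
  diffs <- vapply(1:20, function(seed) {
    pw <- simulate_pwc(d1, seed = seed)
    last <- pw[pw$date_index == final, ]
    mean(last$pwc[last$treatment == "W1"]) - mean(last$pwc[last$treatment == "W5"])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_true(all(diffs > 0))
})

test_that("reflectance simulation respects its contracts", {
  tr <- design_season_one()$treatments[1, ]
  r1 <- simulate_reflectance(150, tr, coarse_scene, seed = 3)
  expect_identical(r1, simulate_reflectance(150, tr, coarse_scene, seed = 3))
  expect_true(all(r1 > 0 & r1 <= 1))
  expect_error(simulate_reflectance(-10, tr, coarse_scene, seed = 1), "positive")
  expect_error(simulate_pwc(structure(list(), class = "pwc_design"), 1))
})

test_that("noise-free reflectance at water band centers strictly decreases in PWC", {
  wl <- coarse_scene$wavelengths_nm
  pwcs <- c(60, 120, 200, 300, 420)
  curves <- sapply(pwcs, function(p) canopy_reflectance(p, 0.1, coarse_scene))
  for (centre in coarse_scene$water_band_centers) {
    j <- which.min(abs(wl - centre))
    expect_true(all(diff(curves[j, ]) < 0),
                label = sprintf("monotone at %g nm", centre))
  }
})

test_that("generated datasets have the design size, grid and invariants", {
  ds1 <- generate_dataset(design_season_one(), coarse_scene, seed = 2)
  expect_equal(dim(ds1$reflectance), c(150, length(coarse_scene$wavelengths_nm)))
  expect_equal(length(ds1$pwc), 150)
  expect_equal(nrow(ds1$metadata), 150)
  # exactly one record per cultivar x treatment x replicate x date
  key <- with(ds1$metadata, table(cultivar, treatment, replicate, date))
  expect_true(all(key == 1))
  expect_false(anyNA(ds1$reflectance))
  expect_true(all(ds1$reflectance > 0 & ds1$reflectance <= 1))
  ds2 <- generate_dataset(design_season_two(), coarse_scene, seed = 2)
  expect_equal(nrow(ds2$reflectance), 120)
  # bit-identical regeneration under the same seed
  expect_identical(ds1, generate_dataset(design_season_one(), coarse_scene, seed = 2))
  # default 1 nm grid from 350 to 2500 has 2151 columns
  expect_length(scene_params()$wavelengths_nm, 2151)
})
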