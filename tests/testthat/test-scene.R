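test_that("make_reference_spectrum places bands where the list says", {
  ax <- build_axis(400, 1800, 701)
  ## thiram's characteristic band
  ref <- make_reference_spectrum(
    data.frame(center = 1380, fwhm = 14, amplitude = 1000), ax)
  nearest <- which.min(abs(unclass(ax) - 1380))
  expect_equal(which.max(ref$spectrum$intensities), nearest)

  zero <- make_reference_spectrum(
    data.frame(center = 1380, fwhm = 14, amplitude = 0), ax)
  expect_true(all(zero$spectrum$intensities == 0))

  ## two non-overlapping Lorentzians: closed-form superposition
  pk <- data.frame(center = c(600, 1500), fwhm = c(10, 16),
                   amplitude = c(800, 500))
  two <- make_reference_spectrum(pk, ax, shape = "lorentzian")
  x <- unclass(ax)
  lor <- function(nu, c0, w, a) a * (w / 2)^2 / ((nu - c0)^2 + (w / 2)^2)
  want <- lor(x, 600, 10, 800) + lor(x, 1500, 16, 500)
  expect_equal(two$spectrum$intensities, want, tolerance = 1e-9)

  expect_error(make_reference_spectrum(
    data.frame(center = 200, fwhm = 10, amplitude = 1), ax), "axis")
  expect_error(make_reference_spectrum(
    data.frame(center = 600, fwhm = 0, amplitude = 1), ax), "FWHM")
})

test_that("gain field has the configured lognormal structure", {
  sc0 <- scene_config(gain = list(log_sd = 0, corr_length_um = 10))
  expect_true(all(make_gain_field(sc0) == 1))

  sc <- scene_config(n_depth = 64L, n_lateral = 64L,
                     gain = list(log_sd = 0.3, corr_length_um = 10))
  sds <- vapply(1:5, function(s) sd(log(make_gain_field(sc, seed = s))), 0)
  expect_true(all(abs(sds - 0.3) / 0.3 < 0.15))
  means <- vapply(1:5, function(s) mean(make_gain_field(sc, seed = s)), 0)
  expect_true(all(abs(means - 1) < 0.02))

  expect_identical(make_gain_field(sc, seed = 7), make_gain_field(sc, seed = 7))
})

test_that("assembled cubes follow the linear mixing model", {
  ## noiseless, gain-free, baseline-free two-component cube is exactly rank 2
  sc <- scene_config(n_depth = 16L, n_lateral = 8L,
                     baseline = list(amplitude = 0, center = 1300,
                                     width = 500, slope = 0),
                     gain = list(log_sd = 0, corr_length_um = 0),
                     target_snr_db = Inf)
  out <- assemble_hypermap(sc, 2)
  d <- svd(out$map$spectra)$d
  expect_lt(d[3], 1e-9 * d[1])

  ## determinism under the scene seed
  out2 <- assemble_hypermap(sc, 2)
  expect_identical(out$map$spectra, out2$map$spectra)

  ## realized SNR within 1 dB of the configured target
  scn <- scene_config(target_snr_db = 25)
  cube <- assemble_hypermap(scn, 4)
  noise <- cube$map$spectra - cube$truth$clean
  snr <- 10 * log10(mean(cube$truth$clean^2) / mean(noise^2))
  expect_lt(abs(snr - 25), 1)
})

test_that("labeled spectra datasets have the declared composition", {
  sc <- scene_config()
  ds <- make_labeled_spectra(sc, 100, seed = 5)
  expect_equal(nrow(ds$X), 300)
  expect_true(all(table(ds$labels) == 100))

  ## zero noise + degenerate dose range: same-class spectra identical
  sc0 <- scene_config(target_snr_db = Inf)
  ds0 <- make_labeled_spectra(sc0, 5, seed = 1, dose_range = c(1, 1))
  for (cl in unique(ds0$labels)) {
    Xc <- ds0$X[ds0$labels == cl, , drop = FALSE]
    expect_equal(max(apply(Xc, 2, function(col) diff(range(col)))), 0)
  }

  ## class structure: within-class correlation exceeds between-class
  ds2 <- make_labeled_spectra(sc, 40, seed = 2)
  cm <- cor(t(ds2$X))
  same <- outer(ds2$labels, ds2$labels, "==")
  diag(same) <- NA
  expect_gt(mean(cm[which(same)], na.rm = TRUE),
            mean(cm[which(!same)], na.rm = TRUE))

  expect_error(make_labeled_spectra(sc, 10, classes = c("nosuch")), "unknown")
  expect_error(make_labeled_spectra(sc, 0), "n_per_class")
})

test_that("scene configuration is validated", {
  expect_error(scene_config(times_h = c(4, 2)), "increasing")
  expect_error(scene_config(gain = list(log_sd = -1, corr_length_um = 5)), "gain")
  comps <- default_scene_components()
  comps[[1]]$dose <- -1
  expect_error(scene_config(components = comps), "doses")
})
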