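test_that("spectrum construction enforces its invariants", {
  expect_error(spectrum(c(500, 400), c(0.1, 0.2)), "increasing")
  expect_error(spectrum(500, 0.1), "at least 2")
  expect_error(spectrum(c(400, 500), c(-0.2, 0.5), "reflectance"), "\\[0, 1\\]")
  expect_error(spectrum(c(400, 500), c(0.5, 1.2), "transmittance"), "\\[0, 1\\]")
  s <- spectrum(c(400, 500), c(0.2, 0.5), "reflectance")
  expect_s3_class(s, "wing_spectrum")
})

test_that("extremum detection finds constructed extrema and skips monotones", {
  wl <- vis_grid(1)
  mono <- spectrum(wl, seq(0.1, 0.9, length.out = length(wl)))
  expect_equal(nrow(find_extrema(mono)), 0)
  # two Gaussians on a flat baseline: maxima at 440/607, one interior min
  v <- 0.05 + 0.3 * exp(-((wl - 440) / 40)^2) + 0.25 * exp(-((wl - 607) / 45)^2)
  s <- spectrum(wl, v)
  ext <- find_extrema(s)
  maxima <- ext[ext$type == "max", ]
  minima <- ext[ext$type == "min", ]
  expect_equal(nrow(maxima), 2)
  expect_equal(maxima$wavelength_nm, c(440, 607), tolerance = 1)
  expect_equal(nrow(minima), 1)
  expect_true(minima$wavelength_nm > 440 && minima$wavelength_nm < 607)
  bs <- bimodal_summary(s)
  expect_equal(bs$peaks$wavelength_nm, c(440, 607), tolerance = 1)
})

test_that("extrema are invariant to value scaling and grid refinement", {
  wl <- vis_grid(2)
  v <- 0.05 + 0.3 * exp(-((wl - 470) / 35)^2) + 0.2 * exp(-((wl - 620) / 50)^2)
  s <- spectrum(wl, v)
  e1 <- find_extrema(s)
  # uniform scaling (scale prominence threshold accordingly)
  s2 <- spectrum(wl, v * 2, "absorbance")
  e2 <- find_extrema(s2, prominence_min = 0.01)
  expect_equal(e1$wavelength_nm, e2$wavelength_nm)
  # refinement by interpolation: positions within one original step
  wl_f <- vis_grid(0.5)
  s3 <- spectrum(wl_f, approx(wl, v, xout = wl_f)$y)
  e3 <- find_extrema(s3)
  expect_equal(nrow(e3), nrow(e1))
  expect_lt(max(abs(e3$wavelength_nm - e1$wavelength_nm)), 2 + 1e-9)
})

test_that("plateau extrema report their midpoint", {
  wl <- seq(400, 500, by = 1)
  v <- rep(0.1, length(wl))
  v[wl >= 440 & wl <= 460] <- 0.5
  ext <- find_extrema(spectrum(wl, v), smoothing_window = 1L)
  expect_equal(ext$wavelength_nm[ext$type == "max"], 450)
})

test_that("detection agrees with an independent peak finder", {
  set.seed(3)
  wl <- vis_grid(1)
  v <- 0.3 + 0.15 * sin(wl / 21) + 0.1 * cos(wl / 47)
  s <- spectrum(wl, v)
  ours <- find_extrema(s, smoothing_window = 1L, prominence_min = 0.02)
  ref <- pracma::findpeaks(v, minpeakheight = -Inf)
  ref_wl <- sort(wl[ref[, 2]])
  ref_wl <- ref_wl[ref_wl > min(wl) & ref_wl < max(wl)]
  ours_max <- ours$wavelength_nm[ours$type == "max"]
  expect_true(all(ours_max %in% ref_wl))
})

test_that("band statistics use trapezoid weighting", {
  wl <- vis_grid(1)
  s <- spectrum(wl, rep(0.85, length(wl)), "transmittance")
  expect_equal(band_stat(s, c(400, 700), "mean"), 0.85, tolerance = 1e-12)
  # linear ramp has mean halfway between the ends regardless of band
  ramp <- spectrum(wl, seq(0, 1, length.out = length(wl)), "transmittance")
  expect_equal(band_stat(ramp, c(400, 700), "mean"), 0.5, tolerance = 1e-9)
  expect_equal(band_stat(ramp, NULL, "min"), 0)
  expect_equal(band_stat(ramp, NULL, "max"), 1)
  expect_error(band_stat(s, c(300, 700)), "outside")
})

test_that("synthetic measured transmittance recovers its generator mean", {
  wl <- vis_grid(1)
  model <- spectrum(wl, rep(0.85, length(wl)), "transmittance")
  meas <- synth_measured_spectrum(model, seed = 202, gain_sd = 0.01,
                                  additive_sd = 0.002)
  expect_lt(abs(band_stat(meas, c(400, 700), "mean") - 0.85), 0.005)
})

test_that("spectrum comparison is symmetric and detects offsets", {
  wl <- vis_grid(1)
  v <- 0.1 + 0.2 * exp(-((wl - 500) / 60)^2)
  a <- spectrum(wl, v)
  self <- compare_spectra(a, a)
  expect_equal(self$max_abs_diff, 0)
  expect_equal(self$rms_diff, 0)
  expect_true(all(self$extrema_offsets_nm == 0))
  b <- spectrum(wl, 0.1 + 0.2 * exp(-((wl - 510) / 60)^2))
  ab <- compare_spectra(a, b)
  ba <- compare_spectra(b, a)
  expect_equal(ab$max_abs_diff, ba$max_abs_diff)
  expect_equal(ab$rms_diff, ba$rms_diff)
  expect_equal(unname(ab$extrema_offsets_nm["max1"]), 10, tolerance = 1)
  disjoint <- spectrum(c(800, 900), c(0.1, 0.2))
  expect_error(compare_spectra(a, disjoint), "disjoint")
})

test_that("band mean of a lossless model's R and T sums to one", {
  wl <- vis_grid(1)
  res <- tmm_spectrum(build_membrane("one-layer", "none")$stack, wl)
  expect_lt(abs(band_stat(res$reflectance, c(400, 700), "mean") +
                  band_stat(res$transmittance, c(400, 700), "mean") - 1),
            1e-9)
})

test_that("spectra survive the CSV round trip", {
  wl <- vis_grid(10)
  s <- spectrum(wl, seq(0.1, 0.8, length.out = length(wl)), "transmittance")
  path <- tempfile(fileext = ".csv")
  write_spectrum_csv(s, path)
  back <- read_spectrum_csv(path)
  expect_equal(back$value, s$value, tolerance = 1e-12)
  expect_equal(attr(back, "kind"), "transmittance")
})
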