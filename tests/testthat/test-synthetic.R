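test_that("measured-spectrum generator is deterministic and unbiased", {
  wl <- vis_grid(5)
  model <- spectrum(wl, 0.4 + 0.3 * sin(wl / 50), "reflectance")
  # zero noise reproduces the model exactly
  clean <- synth_measured_spectrum(model, seed = 1, gain_sd = 0,
                                   additive_sd = 0)
  expect_equal(clean$value, model$value, tolerance = 1e-12)
  # same seed, same spectrum; different seed, different spectrum
  a <- synth_measured_spectrum(model, seed = 7)
  b <- synth_measured_spectrum(model, seed = 7)
  c <- synth_measured_spectrum(model, seed = 8)
  expect_identical(a$value, b$value)
  expect_false(identical(a$value, c$value))
  # generator does not disturb the caller's RNG stream
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(synth_measured_spectrum(model, seed = 7))
  expect_identical(runif(1), before)
})

test_that("replicate averaging converges to the model by the CLT", {
  wl <- vis_grid(10)
  model <- spectrum(wl, rep(0.5, length(wl)), "reflectance")
  gain_sd <- 0.01
  add_sd <- 0.002
  n_rep <- 1000L
  meas <- synth_measured_spectrum(model, seed = 42, gain_sd = gain_sd,
                                  additive_sd = add_sd, replicates = n_rep)
  se <- sqrt((0.5 * gain_sd)^2 + add_sd^2) / sqrt(n_rep)
  expect_lt(max(abs(meas$value - 0.5)), 3.5 * se * sqrt(2))
})

test_that("droplet generator inverts and propagates contract errors", {
  res <- contact_angle(synth_droplet_contour(114, radius = 1))
  expect_lt(abs(res$theta_mean_deg - 114), 1e-6)
  noisy <- contact_angle(synth_droplet_contour(114, radius = 1, seed = 1,
                                               noise_frac = 0.005))
  expect_lt(abs(noisy$theta_mean_deg - 114), 1)
  expect_error(synth_droplet_contour(114, n_points = 5), ">= 10")
  expect_error(synth_droplet_contour(190), "\\(0, 180\\)")
  expect_error(synth_droplet_contour(114, seed = NULL, noise_frac = 0.01),
               "seed")
})

test_that("structure jitter samples the recorded uncertainties", {
  reg <- param_registry()
  # zero scale reproduces the registry
  expect_identical(synth_structure_jitter(reg, seed = 1, sd_scale = 0),
                   reg)
  draws <- vapply(1:100, function(s) {
    synth_structure_jitter(reg, seed = s)$values$h_de
  }, numeric(1))
  # sample mean within 3 standard errors of 436 (sd 20, n 100)
  expect_lt(abs(mean(draws) - 436), 3 * 20 / sqrt(100))
  expect_true(all(draws > 0))
  expect_true(all(abs(draws - 436) <= 3 * 20))
  # parameters without recorded uncertainty stay fixed
  expect_equal(synth_structure_jitter(reg, seed = 2)$values$pitch, 300)
  expect_equal(synth_structure_jitter(reg, seed = 2)$values$n_chitin, 1.56)
})

test_that("membrane extrema are robust to structural non-uniformity", {
  wl <- vis_grid(1)
  nominal <- bimodal_summary(tmm_spectrum(
    build_membrane("three-layer", "none")$stack, wl)$reflectance)
  within <- 0L
  n <- 100L
  for (s in seq_len(n)) {
    reg <- synth_structure_jitter(param_registry(), seed = 2000 + s)
    sm <- try(bimodal_summary(tmm_spectrum(
      build_membrane("three-layer", "none", reg)$stack, wl)$reflectance),
      silent = TRUE)
    if (inherits(sm, "try-error") || is.null(sm$dip)) next
    d <- max(abs(c(sm$peaks$wavelength_nm - nominal$peaks$wavelength_nm,
                   sm$dip$wavelength_nm - nominal$dip$wavelength_nm)))
    if (d <= 25) within <- within + 1L
  }
  expect_gte(within / n, 0.90)
})

test_that("emitted CSVs are byte-identical under a fixed seed", {
  wl <- vis_grid(5)
  model <- spectrum(wl, rep(0.6, length(wl)), "reflectance")
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  write_spectrum_csv(synth_measured_spectrum(model, seed = 31), p1)
  write_spectrum_csv(synth_measured_spectrum(model, seed = 31), p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})
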