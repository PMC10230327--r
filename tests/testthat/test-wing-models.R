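test_that("membrane builders assemble the measured geometry", {
  m3 <- build_membrane("three-layer", "none")
  th <- vapply(m3$stack$layers, `[[`, numeric(1), "thickness_nm")
  expect_equal(th, c(436, 194, 412))
  mats <- vapply(m3$stack$layers, function(l) l$material$name, character(1))
  expect_equal(mats, c("chitin", "pigment", "chitin"))
  m1 <- build_membrane("one-layer", "none")
  expect_equal(m1$stack$layers[[1]]$thickness_nm, 436 + 194 + 412)
  expect_equal(m1$stack$layers[[1]]$material$name, "chitin")
  # nippled raster carries half-ellipses: width 135 at the base row,
  # vanishing at the tip, one per 300 nm period
  mn <- build_membrane("three-layer", "dorsal")
  nmap <- clearwing:::rasterize_structure(mn$structure, 5, 550)
  expect_equal(nrow(nmap), 60) # 300 / 5
  base_row <- sum(Re(nmap[, 28]) > 1) * 5 # just above the base (z=137.5)
  expect_equal(base_row, 135, tolerance = 15)
  tip_row <- sum(Re(nmap[, 1]) > 1) * 5
  expect_lt(tip_row, 60)
  expect_true(all(Re(nmap[, 40]) == 1.56)) # inside dorsal exocuticle
})

test_that("three-layer reflectance is bimodal at the printed extrema", {
  res <- tmm_spectrum(build_membrane("three-layer", "none")$stack,
                      vis_grid(1))
  s <- bimodal_summary(res$reflectance)
  # frozen from this model; the printed study values are 440 / 543 / 607
  expect_equal(s$peaks$wavelength_nm, c(443, 602))
  expect_equal(s$dip$wavelength_nm, 549)
})

test_that("membrane asymmetry is optically unimportant", {
  wl <- vis_grid(1)
  ref <- bimodal_summary(tmm_spectrum(
    build_membrane("three-layer", "none")$stack, wl)$reflectance)
  sym <- bimodal_summary(tmm_spectrum(
    build_membrane("three-layer", "none",
                   param_registry(h_de = 424, h_ve = 424))$stack,
    wl)$reflectance)
  expect_lt(max(abs(ref$peaks$wavelength_nm - sym$peaks$wavelength_nm)), 10)
  expect_lt(abs(ref$dip$wavelength_nm - sym$dip$wavelength_nm), 10)
})

test_that("one-layer model has more prominent peaks than three-layer", {
  wl <- vis_grid(1)
  p1 <- prominent_maxima(tmm_spectrum(
    build_membrane("one-layer", "none")$stack, wl)$reflectance)
  p3 <- prominent_maxima(tmm_spectrum(
    build_membrane("three-layer", "none")$stack, wl)$reflectance)
  expect_gt(nrow(p1), nrow(p3))
})

test_that("interridge model peaks near 520 nm and blue-shifts with gap", {
  res <- tmm_spectrum(build_interridge(), vis_grid(1))
  ext <- find_extrema(res$reflectance)
  maxima <- ext[ext$type == "max", ]
  expect_equal(nrow(maxima), 1) # single prominent maximum
  expect_gt(maxima$wavelength_nm, 500)
  expect_lt(maxima$wavelength_nm, 540)
  sweep <- microrib_spacing_sweep(c(40, 58, 80, 120))
  expect_true(all(diff(sweep$peak_nm) <= 0))
  expect_equal(sweep$peak_nm[2], maxima$wavelength_nm)
  # determinism: identical gaps give identical peaks
  twice <- microrib_spacing_sweep(c(58, 58))
  expect_equal(twice$peak_nm[1], twice$peak_nm[2])
})

test_that("ridge model requires its unmeasured geometry", {
  expect_error(build_ridge(), "h_air_nm")
  expect_error(build_ridge(200), "lamella_nm")
  stk <- build_ridge(150, 80)
  wl <- vis_grid(5)
  res <- tmm_spectrum(stk, wl)
  expect_lt(max(abs(res$reflectance$value + res$transmittance$value +
                      res$absorbance$value - 1)), 1e-9)
  # vanishing air gap converges to the merged chitin slab
  thin <- tmm_spectrum(build_ridge(1e-6, 80), wl)
  merged <- tmm_spectrum(optical_stack(layer(material_chitin(), 305)), wl)
  expect_lt(max(abs(thin$reflectance$value - merged$reflectance$value)),
            1e-3)
})

test_that("a scanned ridge geometry reproduces the short-wavelength peak", {
  # regression fixture located by a grid scan over (h_air, lamella): this
  # geometry places a reflectance maximum at 411 nm (alongside a 520 nm
  # one, echoing the two-peak measurement of the ridge region)
  res <- tmm_spectrum(build_ridge(h_air_nm = 430, lamella_nm = 240),
                      vis_grid(1))
  ext <- find_extrema(res$reflectance)
  maxima <- ext[ext$type == "max", ]
  expect_true(any(abs(maxima$wavelength_nm - 411) <= 3))
  blue <- maxima[which.min(abs(maxima$wavelength_nm - 411)), ]
  expect_equal(blue$value, 0.2402, tolerance = 1e-3)
})

test_that("membrane thicknesses are recoverable from reflectance", {
  wl <- vis_grid(2)
  target <- tmm_spectrum(build_membrane("three-layer", "none")$stack,
                         wl)$reflectance
  fit <- fit_membrane_thicknesses(target)
  expect_lt(abs(fit$h_de - 436), 2)
  expect_lt(abs(fit$h_m - 194), 2)
  expect_lt(abs(fit$h_ve - 412), 2)
  expect_lte(fit$residual, fit$residual_at_defaults + 1e-12)
  # 1% multiplicative noise, seeded: recovery within 10 nm
  noisy <- synth_measured_spectrum(target, seed = 5, gain_sd = 0.01,
                                   additive_sd = 0)
  fitn <- fit_membrane_thicknesses(noisy)
  expect_lt(abs(fitn$h_de - 436), 10)
  expect_lt(abs(fitn$h_m - 194), 10)
  expect_lt(abs(fitn$h_ve - 412), 10)
  # bounds pinned at the defaults return the defaults
  pin <- list(h_de = c(436, 436), h_m = c(194, 194), h_ve = c(412, 412))
  fitp <- fit_membrane_thicknesses(target, bounds = pin)
  expect_equal(c(fitp$h_de, fitp$h_m, fitp$h_ve), c(436, 194, 412))
  expect_equal(fitp$residual, fitp$residual_at_defaults, tolerance = 1e-12)
})

test_that("registry validates and accepts overrides", {
  reg <- param_registry(h_de = 440)
  expect_equal(reg$values$h_de, 440)
  expect_equal(reg$values$h_m, 194)
  expect_error(param_registry(bogus = 1), "unknown")
  expect_error(param_registry(h_m = -3), "> 0")
})
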