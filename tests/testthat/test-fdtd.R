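# FDTD runs here use modest bands so the whole file stays fast; the
# planar-structure transfer-matrix solution is the exact oracle throughout.

test_that("an empty domain transmits everything", {
  v <- run_fdtd_spectrum(fdtd_structure(300, list(), "vacuum"),
                         seq(400, 700, 25))
  expect_lt(max(v$reflectance$value), 0.005)
  expect_true(all(v$transmittance$value > 0.995 &
                    v$transmittance$value < 1.005))
})

test_that("planar slabs match the transfer matrix in both polarizations", {
  wl <- seq(400, 700, 10)
  slab <- fdtd_structure(300, list(fdtd_slab(0, 435, material_chitin())),
                         "slab435")
  oracle <- tmm_spectrum(optical_stack(layer(material_chitin(), 435)), wl)
  for (pol in c("TM", "TE")) {
    f <- run_fdtd_spectrum(slab, wl, polarization = pol)
    expect_lt(max(abs(f$reflectance$value - oracle$reflectance$value)),
              0.01)
    expect_lt(max(abs(f$transmittance$value - oracle$transmittance$value)),
              0.01)
    # lossless energy conservation at the 1% level
    expect_lt(max(abs(f$reflectance$value + f$transmittance$value - 1)),
              0.01)
  }
})

test_that("random planar stacks match the transfer matrix", {
  set.seed(19)
  wl <- seq(420, 680, 20)
  for (rep in 1:3) {
    n_layers <- sample(1:3, 1)
    mats <- lapply(seq_len(n_layers), function(i) {
      optical_material(sprintf("m%d", i), runif(1, 1.2, 1.7))
    })
    th <- round(runif(n_layers, 60, 300) / 5) * 5 # grid-aligned
    z0 <- cumsum(c(0, th))[seq_len(n_layers)]
    els <- lapply(seq_len(n_layers), function(i) {
      fdtd_slab(z0[i], z0[i] + th[i], mats[[i]])
    })
    stk <- optical_stack(lapply(seq_len(n_layers), function(i) {
      layer(mats[[i]], th[i])
    }))
    f <- run_fdtd_spectrum(fdtd_structure(300, els, "rand"), wl)
    o <- tmm_spectrum(stk, wl)
    expect_lt(max(abs(f$reflectance$value - o$reflectance$value)), 0.01)
    expect_lt(max(abs(f$transmittance$value - o$transmittance$value)), 0.01)
  }
})

test_that("transmission is reciprocal for a lossless asymmetric stack", {
  wl <- seq(450, 650, 25)
  m1 <- optical_material("a", 1.3)
  m2 <- optical_material("b", 1.6)
  fwd <- fdtd_structure(300, list(fdtd_slab(0, 150, m1),
                                  fdtd_slab(150, 400, m2)), "fwd")
  rev <- fdtd_structure(300, list(fdtd_slab(0, 250, m2),
                                  fdtd_slab(250, 400, m1)), "rev")
  tf <- run_fdtd_spectrum(fwd, wl)$transmittance$value
  tr <- run_fdtd_spectrum(rev, wl)$transmittance$value
  expect_lt(max(abs(tf - tr)), 0.01)
})

test_that("halving the spatial step barely changes the spectrum", {
  wl <- seq(450, 650, 25)
  slab <- fdtd_structure(300, list(fdtd_slab(0, 435, material_chitin())),
                         "slab435")
  r5 <- run_fdtd_spectrum(slab, wl, dx_nm = 5)$reflectance$value
  r25 <- run_fdtd_spectrum(slab, wl, dx_nm = 2.5)$reflectance$value
  expect_lt(max(abs(r5 - r25)), 0.005)
})

test_that("steady-state fields reproduce Fresnel amplitudes", {
  # all-air: nothing reflected, everything transmitted
  fm0 <- steady_state_field(fdtd_structure(300, list(), "vac"), 550)
  expect_lt(fm0$reflected_magnitude, 0.01)
  expect_equal(fm0$transmitted_magnitude, 1, tolerance = 0.01)
  expect_true(all(is.finite(fm0$magnitude)) && all(fm0$magnitude >= 0))
  # thick absorbing chitin approximates the half-space: reflected
  # amplitude is the front-face Fresnel coefficient (k large enough that
  # the back face is invisible), close to |1 - 1.56| / (1 + 1.56) ~ 0.219
  nk <- 1.56 + 0.12i
  ch_abs <- optical_material("chitin-lossy", 1.56, 0.12)
  hs <- fdtd_structure(300, list(fdtd_slab(0, 2000, ch_abs)), "halfspace")
  fm <- steady_state_field(hs, 550)
  expect_lt(abs(fm$reflected_magnitude - Mod((1 - nk) / (1 + nk))), 0.015)
  # planar slab: reflected magnitude equals sqrt(R) from the TMM oracle
  slab <- fdtd_structure(300, list(fdtd_slab(0, 435, material_chitin())),
                         "slab435")
  fs <- steady_state_field(slab, 550)
  R <- tmm_spectrum(optical_stack(layer(material_chitin(), 435)),
                    c(550, 551))$reflectance$value[1]
  expect_equal(fs$reflected_magnitude, sqrt(R), tolerance = 0.02)
})

test_that("invalid simulation setups fail loudly", {
  slab <- fdtd_structure(300, list(fdtd_slab(0, 435, material_chitin())),
                         "slab")
  expect_error(run_fdtd_spectrum(slab, seq(400, 700, 10), dx_nm = 20),
               "too coarse")
  expect_error(run_fdtd_spectrum(slab, seq(400, 700, 10), courant = 0.9),
               "stability")
  expect_error(run_fdtd_spectrum(slab, seq(300, 700, 10)), "350")
  expect_error(run_fdtd_spectrum(slab, seq(400, 700, 10), npml = 4L),
               "npml")
  # truncation is an explicit failure, never silent
  expect_error(run_fdtd_spectrum(slab, seq(400, 700, 10), max_steps = 900L),
               "did not decay")
})
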