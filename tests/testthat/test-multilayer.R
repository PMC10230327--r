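test_that("bare interfaces and canonical slabs match closed forms", {
  # no interface at all: full transmission
  s0 <- tmm_spectrum(optical_stack(), vis_grid(50))
  expect_equal(s0$reflectance$value, rep(0, 7), tolerance = 1e-12)
  expect_equal(s0$transmittance$value, rep(1, 7), tolerance = 1e-12)
  # single air/chitin interface: Fresnel
  s1 <- tmm_spectrum(optical_stack(substrate = material_chitin()),
                     vis_grid(50))
  expect_equal(s1$reflectance$value, rep(((1.56 - 1) / (1.56 + 1))^2, 7),
               tolerance = 1e-12)
  # half-wave absentee layer at 600 nm
  d_half <- 600 / (2 * 1.56)
  s2 <- tmm_spectrum(optical_stack(layer(material_chitin(), d_half)),
                     c(600, 650))
  expect_equal(s2$reflectance$value[1], 0, tolerance = 1e-10)
  # quarter-wave slab at 600 nm: Airy closed form ((n^2-1)/(n^2+1))^2
  d_quarter <- 600 / (4 * 1.56)
  s3 <- tmm_spectrum(optical_stack(layer(material_chitin(), d_quarter)),
                     c(600, 650))
  expect_equal(s3$reflectance$value[1],
               ((1.56^2 - 1) / (1.56^2 + 1))^2, tolerance = 1e-10)
})

test_that("transfer matrix and Airy oracle agree on single slabs", {
  wl <- seq(350, 950, by = 5)
  for (d in c(150, 436, 1042)) {
    stk <- optical_stack(layer(material_chitin(), d))
    expect_lt(max(abs(tmm_spectrum(stk, wl)$reflectance$value -
                        airy_slab_reflectance(1.56, d, wl))), 1e-10)
  }
  # index-matched slab reflects nothing
  expect_equal(airy_slab_reflectance(1, 500, vis_grid(100)),
               rep(0, 4), tolerance = 1e-14)
})

test_that("energy is conserved and lossless stacks are reversible", {
  set.seed(42)
  wl <- vis_grid(25)
  for (rep in 1:8) {
    lossy <- rep %% 2 == 0
    stk <- random_stack(sample(1:10, 1), lossy = lossy)
    res <- tmm_spectrum(stk, wl)
    total <- res$reflectance$value + res$transmittance$value +
      res$absorbance$value
    expect_lt(max(abs(total - 1)), 1e-9)
    if (!lossy) {
      expect_lt(max(abs(res$absorbance$value)), 1e-9)
      rev_res <- tmm_spectrum(reverse_stack(stk), wl)
      expect_lt(max(abs(res$reflectance$value - rev_res$reflectance$value)),
                1e-9)
    }
  }
})

test_that("splitting a layer into sublayers changes nothing", {
  set.seed(7)
  wl <- vis_grid(25)
  stk <- random_stack(4)
  split_layers <- unlist(lapply(stk$layers, function(ly) {
    list(layer(ly$material, ly$thickness_nm * 0.37),
         layer(ly$material, ly$thickness_nm * 0.63))
  }), recursive = FALSE)
  a <- tmm_spectrum(stk, wl)
  b <- tmm_spectrum(optical_stack(split_layers), wl)
  expect_lt(max(abs(a$reflectance$value - b$reflectance$value)), 1e-10)
  expect_lt(max(abs(a$transmittance$value - b$transmittance$value)), 1e-10)
})

test_that("stack construction is validated", {
  expect_error(layer(material_chitin(), 0), "> 0")
  expect_error(optical_stack(substrate = material_pigment()),
               "non-absorbing")
  expect_error(tmm_spectrum(optical_stack(), numeric(0)), "empty")
  expect_error(tmm_spectrum(optical_stack(), c(500, 450)), "increasing")
})

test_that("stacks round-trip through the YAML reader", {
  path <- system.file("extdata", "models", "membrane_three_layer.yaml",
                      package = "clearwing")
  stk <- read_stack_yaml(path)
  expect_length(stk$layers, 3)
  expect_equal(stk$layers[[2]]$thickness_nm, 194)
  built <- build_membrane("three-layer", "none")$stack
  wl <- vis_grid(10)
  expect_equal(tmm_spectrum(stk, wl)$reflectance$value,
               tmm_spectrum(built, wl)$reflectance$value, tolerance = 1e-12)
})
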