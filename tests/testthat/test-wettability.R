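test_that("contact angles follow spherical-cap geometry", {
  # exact semicircle centered on the baseline: 90 degrees
  semi <- synth_droplet_contour(90, radius = 2)
  r90 <- contact_angle(semi)
  expect_equal(r90$theta_mean_deg, 90, tolerance = 1e-6)
  expect_equal(r90$theta_left_deg, r90$theta_right_deg)
  # center at r/2 above the baseline: theta = 90 + asin(1/2) = 120
  r120 <- contact_angle(synth_droplet_contour(120, radius = 1.5))
  expect_equal(r120$theta_mean_deg, 120, tolerance = 1e-6)
  expect_lt(r120$residual_rms, 1e-9)
})

test_that("noiseless recovery is exact across the angle sweep", {
  for (theta in c(60, 90, 114, 145, 170)) {
    res <- contact_angle(synth_droplet_contour(theta, radius = 1))
    expect_lt(abs(res$theta_mean_deg - theta), 0.1)
  }
})

test_that("noisy recovery stays within a degree", {
  for (theta in c(60, 90, 114, 145, 170)) {
    cont <- synth_droplet_contour(theta, radius = 1, seed = 100 + theta,
                                  noise_frac = 0.005)
    res <- contact_angle(cont)
    expect_lt(abs(res$theta_mean_deg - theta), 1)
  }
})

test_that("contact angle is invariant to scaling and translation", {
  base <- synth_droplet_contour(132, radius = 1, seed = 9,
                                noise_frac = 0.003)
  ref <- contact_angle(base)$theta_mean_deg
  p <- base$points
  moved <- droplet_contour(data.frame(x = 250 * p$x + 1000,
                                      y = 250 * p$y + 500),
                           baseline = 250 * base$baseline + 500)
  expect_equal(contact_angle(moved)$theta_mean_deg, ref, tolerance = 1e-9)
})

test_that("degenerate contours are rejected", {
  expect_error(droplet_contour(data.frame(x = 1:5, y = rep(1, 5))),
               ">= 10 points")
  line <- data.frame(x = seq(0, 1, length.out = 20), y = rep(1, 20))
  expect_error(contact_angle(droplet_contour(line, baseline = 0)),
               "collinear")
  # circle floating above the baseline has no contact line
  phi <- seq(0, 2 * pi, length.out = 50)
  float <- droplet_contour(data.frame(x = cos(phi), y = 5 + sin(phi)),
                           baseline = 0)
  expect_error(contact_angle(float), "intersect")
})

test_that("group comparison matches the t distribution oracle", {
  # worked example: paired differences 1..5
  b <- c(10, 20, 30, 40, 50)
  a <- b + 1:5
  res <- compare_groups(a, b, paired = TRUE)
  oracle <- t_oracle(1:5)
  expect_equal(res$t, 4.242640687, tolerance = 1e-8)
  expect_equal(res$t, oracle$t, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  expect_equal(res$p, 0.01324, tolerance = 1e-3)
  # symmetric zero-mean differences: t = 0, p = 1
  z <- compare_groups(c(-1, 1, -2, 2, 0) + 7, rep(7, 5), paired = TRUE)
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  # unpaired pooled-variance degrees of freedom
  u <- compare_groups(c(1, 2, 3), c(4, 5, 6, 7), paired = FALSE)
  expect_equal(u$df, 5)
  # degenerate data
  expect_equal(compare_groups(rep(1, 3), rep(1, 3), paired = TRUE)$p, 1)
  expect_error(compare_groups(rep(1, 3), rep(2, 3), paired = TRUE),
               "degenerate")
  expect_error(compare_groups(1, 1:3), "n >= 2")
})

test_that("wettability classification uses exclusive thresholds", {
  expect_equal(classify_wettability(c(45, 93, 145, 150, 150.01)),
               c("hydrophilic", "hydrophobic", "hydrophobic", "hydrophobic",
                 "superhydrophobic"))
  expect_equal(classify_wettability(90), "hydrophilic")
  expect_error(classify_wettability(0), "\\(0, 180\\)")
  expect_error(classify_wettability(180), "\\(0, 180\\)")
})

test_that("study-like groups order black > transparent > bare membrane", {
  # synthetic groups at the study means/sds (145/3.2, 114/6.9, 93/11.1),
  # n = 5 droplets, angles re-extracted from noisy contours
  ok <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    rep_ <- run_wettability_analysis(seed = s, noise_frac = 0.003)
    m <- rep_$group_stats$mean_deg
    if (m[1] > m[2] && m[2] > m[3]) ok <- ok + 1L
  }
  expect_gte(ok / n_seeds, 0.99)
})

test_that("contours round-trip through CSV with a baseline header", {
  cont <- synth_droplet_contour(114, radius = 1, seed = 4,
                                noise_frac = 0.002, baseline = 0.3)
  path <- tempfile(fileext = ".csv")
  writeLines(c("# baseline: 0.3", "x,y",
               sprintf("%.10f,%.10f", cont$points$x, cont$points$y)), path)
  back <- read_contour_csv(path)
  expect_equal(contact_angle(back)$theta_mean_deg,
               contact_angle(cont)$theta_mean_deg, tolerance = 1e-9)
  expect_error(read_contour_csv("nope.csv"), "not found")
})
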