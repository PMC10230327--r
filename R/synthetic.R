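#' Synthetic measured spectrum
#'
#' Emulates a microspectrophotometer measurement of a model spectrum:
#' each of `replicates` replicate spectra is the model distorted by a
#' per-replicate multiplicative gain (`Normal(1, gain_sd)`) plus
#' independent per-point additive noise (`Normal(0, additive_sd)`); the
#' replicates are averaged (three by default, mirroring standard practice
#' of averaging measurements from different sample locations) and the
#' result is clipped to the physical range of the spectrum kind. The same
#' seed always reproduces the same spectrum, and the generator leaves the
#' caller's RNG state untouched.
#'
#' @param model A [spectrum()] (the noiseless model prediction).
#' @param seed Required integer seed.
#' @param gain_sd Standard deviation of the multiplicative gain
#'   (default 0.01).
#' @param additive_sd Standard deviation of the additive noise, in value
#'   units (default 0.002).
#' @param replicates Number of averaged replicates (default 3).
#' @return A [spectrum()] of the same kind, with provenance recording the
#'   generator settings.
#' @export
synth_measured_spectrum <- function(model, seed, gain_sd = 0.01,
                                    additive_sd = 0.002, replicates = 3L) {
  stopifnot(inherits(model, "wing_spectrum"))
  check_number(gain_sd, "gain_sd", lower = 0)
  check_number(additive_sd, "additive_sd", lower = 0)
  check_number(replicates, "replicates", lower = 1)
  replicates <- as.integer(replicates)
  n <- nrow(model)
  value <- with_local_seed(seed, {
    acc <- numeric(n)
    for (r in seq_len(replicates)) {
      gain <- rnorm(1L, mean = 1, sd = gain_sd)
      eps <- rnorm(n, mean = 0, sd = additive_sd)
      acc <- acc + gain * model$value + eps
    }
    acc / replicates
  })
  kind <- attr(model, "kind")
  value <- if (kind %in% c("reflectance", "transmittance")) {
    pmin(pmax(value, 0), 1)
  } else {
    pmax(value, 0)
  }
  spectrum(model$wavelength_nm, value, kind,
           provenance = c(attr(model, "provenance"),
                          list(synthetic = TRUE, seed = seed,
                               gain_sd = gain_sd, additive_sd = additive_sd,
                               replicates = replicates)))
}

#' Synthetic sessile-droplet contour
#'
#' Samples `n_points` silhouette points from the circular cap of a drop
#' with the requested static contact angle, optionally jittered by
#' isotropic Gaussian coordinate noise. Noiseless output inverts exactly
#' under [contact_angle()].
#'
#' @param theta_deg Target contact angle in degrees, in (0, 180).
#' @param radius Drop radius (arbitrary length unit, default 1).
#' @param n_points Number of contour points (>= 10).
#' @param seed Integer seed; required when `noise_frac > 0`.
#' @param noise_frac Gaussian coordinate noise standard deviation as a
#'   fraction of the radius (default 0, noiseless).
#' @param baseline Substrate line `y` value (default 0).
#' @return A [droplet_contour()].
#' @export
synth_droplet_contour <- function(theta_deg, radius = 1, n_points = 181L,
                                  seed = NULL, noise_frac = 0,
                                  baseline = 0) {
  check_number(theta_deg, "theta_deg")
  if (theta_deg <= 0 || theta_deg >= 180) {
    stop_invalid("`theta_deg` must lie in (0, 180)")
  }
  check_number(radius, "radius")
  if (radius <= 0) stop_invalid("`radius` must be > 0")
  check_number(noise_frac, "noise_frac", lower = 0)
  n_points <- as.integer(n_points)
  # circle center height above the baseline giving the requested angle
  cheight <- radius * sin((theta_deg - 90) * pi / 180)
  psi <- asin(cheight / radius) # contact points at phi = -psi and pi + psi
  phi <- seq(-psi, pi + psi, length.out = n_points)
  x <- radius * cos(phi)
  y <- baseline + cheight + radius * sin(phi)
  if (noise_frac > 0) {
    jitter <- with_local_seed(seed, {
      list(dx = rnorm(n_points, 0, noise_frac * radius),
           dy = rnorm(n_points, 0, noise_frac * radius))
    })
    x <- x + jitter$dx
    y <- y + jitter$dy
  }
  droplet_contour(data.frame(x = x, y = y), baseline = baseline)
}

#' Jittered copies of the structure-parameter registry
#'
#' Samples each measured length from a normal distribution centred on its
#' registry value with the recorded measurement uncertainty as standard
#' deviation, truncated at plus/minus 3 sd and at positivity. Parameters
#' without a recorded uncertainty are left untouched. Used to quantify
#' how sensitive model spectra are to the natural non-uniformity of the
#' cuticle.
#'
#' @param registry A [param_registry()].
#' @param seed Required integer seed.
#' @param sd_scale Multiplier on all uncertainties (0 reproduces the
#'   registry exactly).
#' @return A [param_registry()] with perturbed values.
#' @export
synth_structure_jitter <- function(registry = param_registry(), seed,
                                   sd_scale = 1) {
  stopifnot(inherits(registry, "param_registry"))
  check_number(sd_scale, "sd_scale", lower = 0)
  if (sd_scale == 0) return(registry)
  out <- registry
  out$values <- with_local_seed(seed, {
    vals <- registry$values
    for (nm in names(vals)) {
      s <- registry$sd[[nm]]
      if (is.null(s) || !is.finite(s)) next
      s <- s * sd_scale
      mu <- vals[[nm]]
      repeat {
        draw <- rnorm(1L, mu, s)
        if (abs(draw - mu) <= 3 * s && draw > 0) break
      }
      vals[[nm]] <- draw
    }
    vals
  })
  out
}
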