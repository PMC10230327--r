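#' Describe a half-ellipsoid nipple array
#'
#' The anti-reflective protuberances on the wing-membrane surface, modelled
#' as half ellipsoids of height `height_nm` and basal diameter
#' `diameter_nm`, repeating laterally with period `pitch_nm`. For
#' homogenization the array cross-section is sliced into `n_slices`
#' sublayers of equal thickness.
#'
#' Defaults are the measured wing-membrane values: height 142 nm, diameter
#' 135 nm, pitch 300 nm.
#'
#' @param height_nm Nipple height (> 0).
#' @param diameter_nm Basal diameter (0 < diameter <= pitch).
#' @param pitch_nm Center-to-center spacing (> 0).
#' @param n_slices Number of homogenized sublayers (>= 1, default 32).
#' @return An object of class `nipple_array`.
#' @export
nipple_array <- function(height_nm = 142, diameter_nm = 135, pitch_nm = 300,
                         n_slices = 32L) {
  check_number(height_nm, "height_nm")
  check_number(diameter_nm, "diameter_nm")
  check_number(pitch_nm, "pitch_nm")
  check_number(n_slices, "n_slices", lower = 1)
  if (height_nm <= 0) stop_invalid("`height_nm` must be > 0")
  if (diameter_nm <= 0 || diameter_nm > pitch_nm) {
    stop_invalid("need 0 < diameter_nm <= pitch_nm (got %g, pitch %g)",
                 diameter_nm, pitch_nm)
  }
  structure(list(height_nm = height_nm, diameter_nm = diameter_nm,
                 pitch_nm = pitch_nm, shape = "half-ellipsoid",
                 n_slices = as.integer(n_slices)),
            class = "nipple_array")
}

#' Describe a microrib layer
#'
#' Periodic chitinous struts (microribs) of rectangular cross-section:
#' thickness `thickness_nm`, width `width_nm`, separated by air gaps of
#' `gap_nm`. Defaults are the measured scale interridge values: 45 / 62 /
#' 58 nm.
#'
#' @param thickness_nm,width_nm,gap_nm Dimensions in nm (all > 0).
#' @param material Rib material (default chitin).
#' @return An object of class `microrib_layer`.
#' @export
microrib_layer <- function(thickness_nm = 45, width_nm = 62, gap_nm = 58,
                           material = material_chitin()) {
  for (v in c(thickness_nm = thickness_nm, width_nm = width_nm,
              gap_nm = gap_nm)) {
    if (!is.finite(v) || v <= 0) {
      stop_invalid("all microrib dimensions must be > 0")
    }
  }
  stopifnot(inherits(material, "optical_material"))
  structure(list(thickness_nm = thickness_nm, width_nm = width_nm,
                 gap_nm = gap_nm, material = material),
            class = "microrib_layer")
}

#' Sliced fill-fraction profile of a nipple array
#'
#' Homogenizes the two-dimensional cross-section of the array: at height
#' `z` above the base a half-ellipse of basal width `d` and height `h` has
#' width `w(z) = d * sqrt(1 - (z/h)^2)`, giving line fill fraction
#' `f(z) = w(z) / pitch`. Each slice is evaluated at its midpoint height.
#' Slices are ordered base to tip.
#'
#' @param nipples A [nipple_array()].
#' @return `data.frame` with columns `thickness_nm` and `fill` (in
#'   `[0, 1]`, non-increasing from base to tip); thicknesses sum to the
#'   nipple height.
#' @export
fill_fraction_profile <- function(nipples) {
  stopifnot(inherits(nipples, "nipple_array"))
  ns <- nipples$n_slices
  dz <- nipples$height_nm / ns
  z_mid <- (seq_len(ns) - 0.5) * dz
  w <- nipples$diameter_nm * sqrt(pmax(0, 1 - (z_mid / nipples$height_nm)^2))
  data.frame(thickness_nm = rep(dz, ns), fill = w / nipples$pitch_nm)
}

#' Effective index of a binary mixture
#'
#' Homogenizes a subwavelength mixture of an inclusion in a host at fill
#' fraction `f`. The default `"volume"` rule averages permittivities,
#' `eps_eff = f * eps_inc + (1 - f) * eps_host` (exact for lamellar
#' structures with the electric field along the lamellae, the TM
#' orientation of the 2D solver); `"maxwell-garnett"` treats the inclusion
#' as dilute cylinders in the host. Both rules return an index between the
#' two constituent indices and are continuous in `f`.
#'
#' @param f Fill fraction of the inclusion, in `[0, 1]`.
#' @param inclusion,host [optical_material()]s.
#' @param wavelength_nm Wavelengths at which to evaluate (nm).
#' @param rule `"volume"` (default) or `"maxwell-garnett"`.
#' @return Complex effective index, one value per wavelength.
#' @export
emt_mix <- function(f, inclusion, host, wavelength_nm,
                    rule = c("volume", "maxwell-garnett")) {
  rule <- match.arg(rule)
  check_number(f, "f", lower = 0, upper = 1)
  eps_i <- material_index(inclusion, wavelength_nm)^2
  eps_h <- material_index(host, wavelength_nm)^2
  eps <- switch(rule,
    volume = f * eps_i + (1 - f) * eps_h,
    `maxwell-garnett` = {
      # 2D (cylinder) Maxwell-Garnett
      beta <- (eps_i - eps_h) / (eps_i + eps_h)
      eps_h * (1 + 2 * f * beta / (1 - f * beta))
    })
  sqrt(eps)
}

#' Homogenize a microrib layer into a single effective layer
#'
#' Replaces the rib/air grating by one homogeneous [layer()] of the same
#' thickness with index from [emt_mix()] at line fill fraction
#' `width / (width + gap)`.
#'
#' @param mr A [microrib_layer()].
#' @param ambient Medium filling the gaps (default air).
#' @param rule Mixing rule passed to [emt_mix()].
#' @return A [layer()] whose material carries a constant effective index
#'   (evaluated from the constituent indices, which are constant for the
#'   default materials).
#' @export
microrib_effective_layer <- function(mr, ambient = material_air(),
                                     rule = "volume") {
  stopifnot(inherits(mr, "microrib_layer"))
  f <- mr$width_nm / (mr$width_nm + mr$gap_nm)
  # reference wavelength irrelevant for constant-index constituents
  n_eff <- emt_mix(f, mr$material, ambient, 550, rule = rule)
  if (abs(Im(n_eff)) > 1e-12) {
    stop_invalid("microrib homogenization expects lossless constituents")
  }
  layer(optical_material(sprintf("microrib-emt(f=%.3f)", f), Re(n_eff), 0),
        mr$thickness_nm)
}

#' Graded effective-index layers for a nipple array
#'
#' Converts the sliced fill-fraction profile into a list of homogeneous
#' [layer()]s suitable for [optical_stack()]. Slices are returned in the
#' order light traverses them: `orientation = "up"` (nipples pointing into
#' the ambient, tips struck first) yields tip-to-base order.
#'
#' @param nipples A [nipple_array()].
#' @param material Nipple material (default chitin).
#' @param ambient Surrounding medium (default air).
#' @param orientation `"up"` (tips toward the incidence side) or `"down"`.
#' @param rule Mixing rule passed to [emt_mix()].
#' @return List of [layer()]s.
#' @export
nipple_graded_layers <- function(nipples, material = material_chitin(),
                                 ambient = material_air(),
                                 orientation = c("up", "down"),
                                 rule = "volume") {
  orientation <- match.arg(orientation)
  prof <- fill_fraction_profile(nipples)
  lys <- lapply(seq_len(nrow(prof)), function(i) {
    n_eff <- emt_mix(prof$fill[i], material, ambient, 550, rule = rule)
    layer(optical_material(sprintf("nipple-emt(f=%.4f)", prof$fill[i]),
                           Re(n_eff), 0),
          prof$thickness_nm[i])
  })
  if (orientation == "up") rev(lys) else lys
}
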