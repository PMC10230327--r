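#' Define a layer of an optical stack
#'
#' @param material An [optical_material()].
#' @param thickness_nm Physical thickness in nm (> 0, finite).
#' @return An object of class `layer`.
#' @export
layer <- function(material, thickness_nm) {
  stopifnot(inherits(material, "optical_material"))
  check_number(thickness_nm, "thickness_nm")
  if (thickness_nm <= 0) stop_invalid("`thickness_nm` must be > 0")
  structure(list(material = material, thickness_nm = thickness_nm),
            class = "layer")
}

#' Assemble a planar multilayer stack
#'
#' Light strikes the first element of `layers` first, travelling from the
#' semi-infinite `ambient` medium towards the semi-infinite `substrate`.
#' Ambient and substrate must be lossless (`k = 0`) so that reflectance and
#' transmittance are well defined.
#'
#' @param layers List of [layer()] objects (may be empty for a bare
#'   interface).
#' @param ambient,substrate Lossless [optical_material()]s; both default
#'   to air.
#' @return An object of class `optical_stack`.
#' @export
optical_stack <- function(layers = list(), ambient = material_air(),
                          substrate = material_air()) {
  stopifnot(inherits(ambient, "optical_material"),
            inherits(substrate, "optical_material"))
  if (inherits(layers, "layer")) layers <- list(layers)
  if (!all(vapply(layers, inherits, logical(1), "layer"))) {
    stop_invalid("`layers` must be a list of layer() objects")
  }
  for (m in list(ambient, substrate)) {
    if (any(m$k$value != 0)) {
      stop_invalid("ambient and substrate must be non-absorbing (k = 0); '%s' is not",
                   m$name)
    }
  }
  structure(list(ambient = ambient, layers = layers, substrate = substrate),
            class = "optical_stack")
}

#' @export
print.optical_stack <- function(x, ...) {
  cat(sprintf("<optical_stack> %s | %d layer(s) | %s\n", x$ambient$name,
              length(x$layers), x$substrate$name))
  for (ly in x$layers) {
    cat(sprintf("  %-12s %8.1f nm\n", ly$material$name, ly$thickness_nm))
  }
  invisible(x)
}

#' Reverse the layer order of a stack
#'
#' Swaps ambient and substrate and reverses the layers, i.e. illumination
#' from the opposite side.
#'
#' @param stack An [optical_stack()].
#' @return An [optical_stack()].
#' @export
reverse_stack <- function(stack) {
  stopifnot(inherits(stack, "optical_stack"))
  optical_stack(rev(stack$layers), ambient = stack$substrate,
                substrate = stack$ambient)
}

#' Normal-incidence reflectance/transmittance by the transfer-matrix method
#'
#' Exact characteristic-matrix solution for a planar multilayer at normal
#' incidence. Complex indices follow the `n + i k` convention with `k > 0`
#' meaning absorption. For every wavelength the energy balance
#' `R + T + A = 1` holds to machine precision, with `A` the fraction
#' absorbed in the stack (zero for lossless layers).
#'
#' @param stack An [optical_stack()].
#' @param wavelength_nm Strictly increasing wavelength grid in nm.
#' @return List of three [spectrum()] objects: `reflectance`,
#'   `transmittance` and `absorbance` (the absorbed fraction `1 - R - T`).
#' @examples
#' s <- optical_stack(substrate = material_chitin())
#' tmm_spectrum(s, c(500, 600))$reflectance$value # Fresnel ((0.56/2.56)^2)
#' @export
tmm_spectrum <- function(stack, wavelength_nm) {
  stopifnot(inherits(stack, "optical_stack"))
  check_wavelengths(wavelength_nm)
  rt <- tmm_amplitudes(stack, wavelength_nm)
  R <- Mod(rt$r)^2
  Tt <- rt$n_sub / rt$n_amb * Mod(rt$t)^2
  A <- 1 - R - Tt
  A[abs(A) < 1e-12] <- 0
  if (length(wavelength_nm) == 1L) {
    wavelength_nm <- c(wavelength_nm, wavelength_nm + 1e-6)
    R <- rep(R, 2L); Tt <- rep(Tt, 2L); A <- rep(A, 2L)
  }
  prov <- list(method = "tmm", n_layers = length(stack$layers))
  list(reflectance = spectrum(wavelength_nm, pmin(pmax(R, 0), 1),
                              "reflectance", prov),
       transmittance = spectrum(wavelength_nm, pmin(pmax(Tt, 0), 1),
                                "transmittance", prov),
       absorbance = spectrum(wavelength_nm, pmax(A, 0), "absorbance", prov))
}

# Complex reflection/transmission amplitudes of a stack. Internal core
# shared by tmm_spectrum() and the field/flux conventions of the FDTD
# cross-checks.
tmm_amplitudes <- function(stack, wavelength_nm) {
  nw <- length(wavelength_nm)
  n_amb <- Re(material_index(stack$ambient, wavelength_nm))
  n_sub <- Re(material_index(stack$substrate, wavelength_nm))
  m11 <- rep(1 + 0i, nw); m12 <- rep(0 + 0i, nw)
  m21 <- rep(0 + 0i, nw); m22 <- rep(1 + 0i, nw)
  for (ly in stack$layers) {
    n <- material_index(ly$material, wavelength_nm)
    delta <- 2 * pi * n * ly$thickness_nm / wavelength_nm
    # characteristic matrix for the n + i k, exp(-i w t) convention: the
    # off-diagonal factor is -i (with +i, absorption would act as gain)
    cd <- cos(delta); sd_ <- sin(delta)
    a11 <- cd;             a12 <- -1i * sd_ / n
    a21 <- -1i * n * sd_;  a22 <- cd
    t11 <- m11 * a11 + m12 * a21
    t12 <- m11 * a12 + m12 * a22
    t21 <- m21 * a11 + m22 * a21
    t22 <- m21 * a12 + m22 * a22
    m11 <- t11; m12 <- t12; m21 <- t21; m22 <- t22
  }
  denom <- (m11 + m12 * n_sub) * n_amb + (m21 + m22 * n_sub)
  r <- ((m11 + m12 * n_sub) * n_amb - (m21 + m22 * n_sub)) / denom
  t <- 2 * n_amb / denom
  list(r = r, t = t, n_amb = n_amb, n_sub = n_sub)
}

#' Closed-form Airy reflectance of a single slab in air
#'
#' Independent single-slab oracle: the Airy summation of multiple
#' reflections inside a lossless slab of index `n` and thickness `d_nm`
#' suspended in air,
#' `r = r1 (1 - e^{2 i delta}) / (1 - r1^2 e^{2 i delta})` with
#' `r1 = (1 - n)/(1 + n)` and `delta = 2 pi n d / lambda`. Kept
#' deliberately separate from the transfer-matrix implementation so the
#' two can cross-check each other.
#'
#' @param n Real refractive index of the slab (>= 1).
#' @param d_nm Slab thickness in nm (> 0).
#' @param wavelength_nm Wavelengths in nm.
#' @return Numeric reflectance values.
#' @export
airy_slab_reflectance <- function(n, d_nm, wavelength_nm) {
  check_number(n, "n", lower = 1)
  check_number(d_nm, "d_nm")
  if (d_nm <= 0) stop_invalid("`d_nm` must be > 0")
  if (any(wavelength_nm <= 0)) stop_invalid("wavelengths must be > 0")
  r1 <- (1 - n) / (1 + n)
  phase <- exp(2i * 2 * pi * n * d_nm / wavelength_nm)
  r <- r1 * (1 - phase) / (1 - r1^2 * phase)
  Mod(r)^2
}
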