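#' Define an optical material
#'
#' An optical material carries a (possibly wavelength-dependent) complex
#' refractive index `n + i k`, with the sign convention that `k > 0` means
#' absorption. Both `n` and `k` may be given either as a single constant or
#' as a two-column table (`wavelength_nm`, `value`); tabulated values are
#' linearly interpolated at evaluation time and clamped (with a warning) to
#' the nearest tabulated endpoint outside the tabulated range.
#'
#' The package ships the three media of the wing models as constructors:
#' air (`n = 1`), chitin (`n = 1.56`, lossless) and the melanin-bearing
#' mesocuticle pigment (`n = 1.74` with a small extinction coefficient,
#' `k = 0.010` by default, below the `0.012` visible-range ceiling that
#' keeps the membrane transparent).
#'
#' @param name Character label.
#' @param n_real Real refractive index: a single number `>= 1`, or a
#'   `data.frame` with columns `wavelength_nm` and `value`.
#' @param k_imag Extinction coefficient: a single number `>= 0` (default 0),
#'   or a `data.frame` with columns `wavelength_nm` and `value`.
#' @return An object of class `optical_material`.
#' @examples
#' air <- optical_material("air", 1.0)
#' chitin <- optical_material("chitin", 1.56)
#' material_index(chitin, 550) # 1.56 + 0i
#' @export
optical_material <- function(name, n_real, k_imag = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  n_tab <- as_index_table(n_real, "n_real")
  k_tab <- as_index_table(k_imag, "k_imag")
  if (any(n_tab$value < 1)) {
    stop_invalid("material '%s': n_real must be >= 1 everywhere", name)
  }
  if (any(k_tab$value < 0)) {
    stop_invalid("material '%s': k_imag must be >= 0 everywhere", name)
  }
  structure(list(name = name, n = n_tab, k = k_tab),
            class = "optical_material")
}

as_index_table <- function(x, what) {
  if (is.numeric(x) && length(x) == 1L) {
    if (!is.finite(x)) stop_invalid("`%s` must be finite", what)
    return(data.frame(wavelength_nm = NA_real_, value = x))
  }
  if (is.data.frame(x)) {
    if (!all(c("wavelength_nm", "value") %in% names(x))) {
      stop_invalid("`%s` table needs columns wavelength_nm and value", what)
    }
    x <- x[order(x$wavelength_nm), c("wavelength_nm", "value")]
    if (anyNA(x) || any(!is.finite(as.matrix(x)))) {
      stop_invalid("`%s` table must be finite", what)
    }
    if (any(diff(x$wavelength_nm) <= 0)) {
      stop_invalid("`%s` table wavelengths must be strictly increasing", what)
    }
    return(x)
  }
  stop_invalid("`%s` must be a scalar or a wavelength_nm/value data.frame",
               what)
}

eval_index_table <- function(tab, wavelength_nm, what, name) {
  if (nrow(tab) == 1L && is.na(tab$wavelength_nm[1L])) {
    return(rep(tab$value[1L], length(wavelength_nm)))
  }
  lo <- min(tab$wavelength_nm)
  hi <- max(tab$wavelength_nm)
  if (any(wavelength_nm < lo | wavelength_nm > hi)) {
    warning(sprintf(
      "material '%s': %s evaluated outside tabulated range [%g, %g] nm; clamping to nearest endpoint",
      name, what, lo, hi), call. = FALSE)
  }
  approx(tab$wavelength_nm, tab$value, xout = pmin(pmax(wavelength_nm, lo), hi),
         method = "linear", rule = 2)$y
}

#' Evaluate the complex refractive index of a material
#'
#' @param material An [optical_material()].
#' @param wavelength_nm Numeric vector of wavelengths in nm.
#' @return Complex vector `n + i k`, one element per wavelength.
#' @export
material_index <- function(material, wavelength_nm) {
  stopifnot(inherits(material, "optical_material"))
  if (length(wavelength_nm) == 0L || !is.numeric(wavelength_nm) ||
      any(!is.finite(wavelength_nm)) || any(wavelength_nm <= 0)) {
    stop_invalid("`wavelength_nm` must be positive finite numbers")
  }
  n <- eval_index_table(material$n, wavelength_nm, "n_real", material$name)
  k <- eval_index_table(material$k, wavelength_nm, "k_imag", material$name)
  complex(real = n, imaginary = k)
}

#' @export
print.optical_material <- function(x, ...) {
  n_desc <- if (nrow(x$n) == 1L && is.na(x$n$wavelength_nm[1L])) {
    sprintf("n = %g", x$n$value[1L])
  } else {
    sprintf("n tabulated over [%g, %g] nm", min(x$n$wavelength_nm),
            max(x$n$wavelength_nm))
  }
  k_desc <- if (nrow(x$k) == 1L && is.na(x$k$wavelength_nm[1L])) {
    sprintf("k = %g", x$k$value[1L])
  } else {
    sprintf("k tabulated over [%g, %g] nm", min(x$k$wavelength_nm),
            max(x$k$wavelength_nm))
  }
  cat(sprintf("<optical_material> %s: %s, %s\n", x$name, n_desc, k_desc))
  invisible(x)
}

#' @rdname optical_material
#' @export
material_air <- function() optical_material("air", 1.0, 0.0)

#' @rdname optical_material
#' @export
material_chitin <- function() optical_material("chitin", 1.56, 0.0)

#' @rdname optical_material
#' @param k Extinction coefficient for the pigment material: a constant or
#'   a `wavelength_nm`/`value` table, e.g. from [k_from_absorbance()].
#' @export
material_pigment <- function(k = 0.010) {
  optical_material("pigment", 1.74, k)
}

#' Construct an absorbance spectrum
#'
#' Decadic (base-10) absorbance measured through a known sample thickness,
#' the input to [k_from_absorbance()].
#'
#' @param wavelength_nm Strictly increasing wavelengths, all within
#'   200--1200 nm.
#' @param absorbance Non-negative decadic absorbance values.
#' @param path_thickness_nm Thickness of the material the absorbance was
#'   measured through, in nm (> 0).
#' @return An object of class `absorbance_spectrum`.
#' @export
absorbance_spectrum <- function(wavelength_nm, absorbance, path_thickness_nm) {
  check_wavelengths(wavelength_nm)
  if (any(wavelength_nm < 200) || any(wavelength_nm > 1200)) {
    stop_invalid("absorbance wavelengths must lie within [200, 1200] nm")
  }
  if (length(absorbance) != length(wavelength_nm)) {
    stop_invalid("`absorbance` and `wavelength_nm` lengths differ")
  }
  if (!is.numeric(absorbance) || any(!is.finite(absorbance))) {
    stop_invalid("`absorbance` must be finite numeric values")
  }
  if (any(absorbance < 0)) {
    stop_invalid("`absorbance` must be >= 0 everywhere")
  }
  check_number(path_thickness_nm, "path_thickness_nm")
  if (path_thickness_nm <= 0) {
    stop_invalid("`path_thickness_nm` must be > 0")
  }
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 absorbance = as.numeric(absorbance),
                 path_thickness_nm = path_thickness_nm),
            class = "absorbance_spectrum")
}

#' Extinction coefficient from a decadic absorbance spectrum
#'
#' Applies the Beer--Lambert relation
#' `k(lambda) = ln(10) * A(lambda) * lambda / (4 * pi * d)`,
#' where `A` is the decadic absorbance and `d` the path thickness. The
#' result is linear in `A` and inversely proportional to `d`.
#'
#' @param spec An [absorbance_spectrum()].
#' @return A `data.frame` with columns `wavelength_nm` and `value` (the
#'   extinction coefficient `k`), directly usable as the `k_imag` table of
#'   [optical_material()].
#' @examples
#' a <- absorbance_spectrum(c(400, 500, 600), c(1, 1, 1), 1000)
#' k_from_absorbance(a) # k at 500 nm is ln(10)*500/(4*pi*1000) ~ 0.0916
#' @export
k_from_absorbance <- function(spec) {
  if (!inherits(spec, "absorbance_spectrum")) {
    stop_invalid("`spec` must be an absorbance_spectrum")
  }
  k <- log(10) * spec$absorbance * spec$wavelength_nm /
    (4 * pi * spec$path_thickness_nm)
  data.frame(wavelength_nm = spec$wavelength_nm, value = k)
}

#' Decadic absorbance implied by an extinction-coefficient table
#'
#' Inverse of [k_from_absorbance()]:
#' `A(lambda) = 4 * pi * k(lambda) * d / (ln(10) * lambda)`.
#'
#' @param k_table `data.frame` with columns `wavelength_nm` and `value`.
#' @param path_thickness_nm Path thickness in nm (> 0).
#' @return An [absorbance_spectrum()].
#' @export
absorbance_from_k <- function(k_table, path_thickness_nm) {
  tab <- as_index_table(k_table, "k_table")
  if (nrow(tab) == 1L && is.na(tab$wavelength_nm[1L])) {
    stop_invalid("`k_table` must be tabulated against wavelength")
  }
  check_number(path_thickness_nm, "path_thickness_nm")
  if (path_thickness_nm <= 0) stop_invalid("`path_thickness_nm` must be > 0")
  a <- 4 * pi * tab$value * path_thickness_nm / (log(10) * tab$wavelength_nm)
  absorbance_spectrum(tab$wavelength_nm, a, path_thickness_nm)
}
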