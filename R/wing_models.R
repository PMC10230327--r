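#' Registry of measured wing-structure parameters
#'
#' Central store of the measured geometry of the transparent-wing system
#' and the optical constants used by every model builder. All lengths are
#' in nm; stated measurement uncertainties (one standard deviation) are
#' retained as metadata and drive [synth_structure_jitter()].
#'
#' Defaults: nipple array height 142 (sd 10), diameter 135 (sd 11), pitch
#' 300; dorsal exocuticle 436 (sd 20), pigmented mesocuticle 194 (sd 7),
#' ventral exocuticle 412 (sd 10); microrib thickness 45 (sd 2), width 62
#' (sd 4), gap 58 (sd 3); scale lower lamina 225 (sd 12); chitin index
#' 1.56, air 1.0, pigment real index 1.74 with extinction coefficient
#' 0.010.
#'
#' @param ... Named overrides of any default value (e.g. `h_de = 440`).
#' @return An object of class `param_registry`: list with elements
#'   `values` (named list) and `sd` (named numeric of uncertainties, `NA`
#'   where none was measured).
#' @export
param_registry <- function(...) {
  values <- list(
    h_n = 142, d_n = 135, pitch = 300,
    h_de = 436, h_m = 194, h_ve = 412,
    h_mr = 45, w_mr = 62, gap_mr = 58, h_LL = 225,
    n_chitin = 1.56, n_air = 1.0, n_pigment_real = 1.74, k_pigment = 0.010)
  sds <- c(h_n = 10, d_n = 11, pitch = NA, h_de = 20, h_m = 7, h_ve = 10,
           h_mr = 2, w_mr = 4, gap_mr = 3, h_LL = 12,
           n_chitin = NA, n_air = NA, n_pigment_real = NA, k_pigment = NA)
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(values))
    if (length(unknown)) {
      stop_invalid("unknown registry parameter(s): %s",
                   paste(unknown, collapse = ", "))
    }
    values <- modifyList(values, overrides)
  }
  lengths <- setdiff(names(values),
                     c("n_chitin", "n_air", "n_pigment_real", "k_pigment"))
  for (nm in lengths) {
    if (!is.finite(values[[nm]]) || values[[nm]] <= 0) {
      stop_invalid("registry length `%s` must be > 0", nm)
    }
  }
  if (values$n_chitin < 1 || values$n_pigment_real < 1 || values$n_air < 1) {
    stop_invalid("registry refractive indices must be >= 1")
  }
  if (values$k_pigment < 0) stop_invalid("`k_pigment` must be >= 0")
  structure(list(values = values, sd = sds), class = "param_registry")
}

#' @export
print.param_registry <- function(x, ...) {
  cat("<param_registry>\n")
  for (nm in names(x$values)) {
    sd <- x$sd[[nm]]
    cat(sprintf("  %-16s %8.4g%s\n", nm, x$values[[nm]],
                if (!is.null(sd) && is.finite(sd)) sprintf(" (sd %g)", sd)
                else ""))
  }
  invisible(x)
}

registry_materials <- function(registry, k_pigment_table = NULL) {
  v <- registry$values
  k <- if (is.null(k_pigment_table)) v$k_pigment else k_pigment_table
  list(air = optical_material("air", v$n_air, 0),
       chitin = optical_material("chitin", v$n_chitin, 0),
       pigment = optical_material("pigment", v$n_pigment_real, k))
}

#' Build a wing-membrane optical model
#'
#' Assembles both representations of the membrane: a planar
#' [optical_stack()] for the transfer-matrix solver (the nipple array, if
#' present, enters as a graded effective-medium profile) and an
#' [fdtd_structure()] carrying the literal half-ellipse geometry for the
#' 2D FDTD solver.
#'
#' The `"three-layer"` variant is dorsal exocuticle (chitin) / pigmented
#' mesocuticle / ventral exocuticle (chitin); the `"one-layer"` variant is
#' a single homogeneous chitin slab with the same total thickness.
#' Nipples sit on the dorsal (illuminated) face by default; `"both"`
#' places mirrored arrays on both faces.
#'
#' @param variant `"three-layer"` (default) or `"one-layer"`.
#' @param nipples `"none"`, `"dorsal"` or `"both"`.
#' @param registry A [param_registry()].
#' @param n_slices Sublayers for the graded nipple profile (TMM route).
#' @param k_pigment_table Optional tabulated pigment extinction
#'   coefficient (`wavelength_nm`/`value` data frame), e.g. from
#'   [k_from_absorbance()]; default is the registry constant.
#' @return An object of class `membrane_model`: list with `stack`,
#'   `structure`, `variant`, `nipples`, `registry`.
#' @export
build_membrane <- function(variant = c("three-layer", "one-layer"),
                           nipples = c("none", "dorsal", "both"),
                           registry = param_registry(), n_slices = 32L,
                           k_pigment_table = NULL) {
  variant <- match.arg(variant)
  nipples <- match.arg(nipples)
  stopifnot(inherits(registry, "param_registry"))
  v <- registry$values
  mats <- registry_materials(registry, k_pigment_table)

  core_layers <- if (variant == "three-layer") {
    list(layer(mats$chitin, v$h_de), layer(mats$pigment, v$h_m),
         layer(mats$chitin, v$h_ve))
  } else {
    list(layer(mats$chitin, v$h_de + v$h_m + v$h_ve))
  }

  arr <- nipple_array(v$h_n, v$d_n, v$pitch, n_slices)
  tmm_layers <- core_layers
  if (nipples %in% c("dorsal", "both")) {
    tmm_layers <- c(nipple_graded_layers(arr, mats$chitin, mats$air, "up"),
                    tmm_layers)
  }
  if (nipples == "both") {
    tmm_layers <- c(tmm_layers,
                    nipple_graded_layers(arr, mats$chitin, mats$air, "down"))
  }
  stk <- optical_stack(tmm_layers, ambient = mats$air, substrate = mats$air)

  z <- 0
  elements <- list()
  if (nipples %in% c("dorsal", "both")) {
    elements <- c(elements, list(
      fdtd_nipple_row(z, v$h_n, v$d_n, mats$chitin, "up")))
    z <- z + v$h_n
  }
  if (variant == "three-layer") {
    elements <- c(elements, list(
      fdtd_slab(z, z + v$h_de, mats$chitin),
      fdtd_slab(z + v$h_de, z + v$h_de + v$h_m, mats$pigment),
      fdtd_slab(z + v$h_de + v$h_m, z + v$h_de + v$h_m + v$h_ve,
                mats$chitin)))
    z <- z + v$h_de + v$h_m + v$h_ve
  } else {
    tot <- v$h_de + v$h_m + v$h_ve
    elements <- c(elements, list(fdtd_slab(z, z + tot, mats$chitin)))
    z <- z + tot
  }
  if (nipples == "both") {
    elements <- c(elements, list(
      fdtd_nipple_row(z, v$h_n, v$d_n, mats$chitin, "down")))
    z <- z + v$h_n
  }
  struct <- fdtd_structure(v$pitch, elements,
                           name = sprintf("membrane-%s-%s", variant, nipples))

  structure(list(stack = stk, structure = struct, variant = variant,
                 nipples = nipples, registry = registry),
            class = "membrane_model")
}

#' @export
print.membrane_model <- function(x, ...) {
  cat(sprintf("<membrane_model> %s, nipples: %s (total %g nm)\n", x$variant,
              x$nipples, sum(vapply(x$stack$layers, `[[`, numeric(1),
                                    "thickness_nm"))))
  invisible(x)
}

#' Build the interridge scale model
#'
#' The interridge region of a window scale: a microrib grating homogenized
#' into a single effective layer ([microrib_effective_layer()]) resting on
#' the chitin lower lamina, in air. Its normal-incidence reflectance shows
#' a single prominent maximum near 520 nm for the measured dimensions.
#'
#' @param registry A [param_registry()].
#' @param rule Effective-medium mixing rule (see [emt_mix()]).
#' @return An [optical_stack()].
#' @export
build_interridge <- function(registry = param_registry(), rule = "volume") {
  stopifnot(inherits(registry, "param_registry"))
  v <- registry$values
  mats <- registry_materials(registry)
  mr <- microrib_layer(v$h_mr, v$w_mr, v$gap_mr, mats$chitin)
  optical_stack(list(microrib_effective_layer(mr, mats$air, rule),
                     layer(mats$chitin, v$h_LL)),
                ambient = mats$air, substrate = mats$air)
}

#' Build the ridge scale model
#'
#' Multilayer interference model of a scale ridge: a chitin lamella
#' suspended over an air gap above the chitin lower lamina. Neither the
#' lamella thickness nor the air-gap thickness was measured directly, so
#' both are required inputs with no defaults.
#'
#' @param h_air_nm Air-gap thickness in nm (required, > 0).
#' @param lamella_nm Lamella thickness in nm (required, > 0).
#' @param registry A [param_registry()].
#' @return An [optical_stack()] `[chitin lamella | air gap | lower
#'   lamina]` in air.
#' @export
build_ridge <- function(h_air_nm, lamella_nm, registry = param_registry()) {
  if (missing(h_air_nm) || is.null(h_air_nm)) {
    stop_invalid("`h_air_nm` is required for the ridge model (no measured default)")
  }
  if (missing(lamella_nm) || is.null(lamella_nm)) {
    stop_invalid("`lamella_nm` is required for the ridge model (no measured default)")
  }
  check_number(h_air_nm, "h_air_nm")
  check_number(lamella_nm, "lamella_nm")
  if (h_air_nm <= 0 || lamella_nm <= 0) {
    stop_invalid("ridge thicknesses must be > 0")
  }
  stopifnot(inherits(registry, "param_registry"))
  v <- registry$values
  mats <- registry_materials(registry)
  optical_stack(list(layer(mats$chitin, lamella_nm),
                     layer(mats$air, h_air_nm),
                     layer(mats$chitin, v$h_LL)),
                ambient = mats$air, substrate = mats$air)
}

#' Reflectance-peak position versus microrib spacing
#'
#' Recomputes the interridge model for each rib gap and reports the
#' wavelength of the most prominent reflectance maximum in the band. With
#' rising gap the chitin fill fraction falls, the effective index of the
#' rib layer drops, and the peak moves to shorter wavelengths
#' (a blue-shift), so the peak list is non-increasing.
#'
#' @param gaps_nm Ascending rib gaps in nm (> 0).
#' @param registry A [param_registry()].
#' @param band Wavelength band `c(min, max)` in nm.
#' @param step_nm Grid step for the TMM sweep.
#' @return `data.frame` with columns `gap_nm` and `peak_nm`.
#' @export
microrib_spacing_sweep <- function(gaps_nm, registry = param_registry(),
                                   band = c(400, 700), step_nm = 1) {
  if (length(gaps_nm) == 0L || any(!is.finite(gaps_nm)) || any(gaps_nm <= 0)) {
    stop_invalid("`gaps_nm` must be positive finite values")
  }
  if (is.unsorted(gaps_nm)) stop_invalid("`gaps_nm` must be ascending")
  wl <- seq(band[1L], band[2L], by = step_nm)
  peaks <- vapply(gaps_nm, function(g) {
    reg <- registry
    reg$values$gap_mr <- g
    s <- tmm_spectrum(build_interridge(reg), wl)$reflectance
    ext <- find_extrema(s)
    maxima <- ext[ext$type == "max", , drop = FALSE]
    if (nrow(maxima) == 0L) return(NA_real_)
    maxima$wavelength_nm[which.max(maxima$prominence)]
  }, numeric(1))
  data.frame(gap_nm = gaps_nm, peak_nm = peaks)
}

#' Fit membrane layer thicknesses to a target reflectance spectrum
#'
#' Bounded least-squares estimation of the three membrane thicknesses
#' (dorsal exocuticle, mesocuticle, ventral exocuticle) from a measured or
#' synthetic reflectance spectrum: a coarse grid scan over the bounds
#' followed by local `L-BFGS-B` refinement of the sum of squared
#' residuals. Deterministic for fixed inputs.
#'
#' @param target A reflectance [spectrum()] on a 400--700 nm (or
#'   narrower) grid.
#' @param bounds Named list with elements `h_de`, `h_m`, `h_ve`, each
#'   `c(lower, upper)`; defaults to the registry values plus/minus their
#'   recorded uncertainties.
#' @param registry A [param_registry()].
#' @param nipples Membrane nipple option used during fitting (must match
#'   how the target was produced).
#' @param n_grid Coarse grid points per dimension (default 5).
#' @return List with `h_de`, `h_m`, `h_ve` (fitted nm), `residual` (sum
#'   of squares at the optimum) and `residual_at_defaults`.
#' @export
fit_membrane_thicknesses <- function(target, bounds = NULL,
                                     registry = param_registry(),
                                     nipples = "none", n_grid = 5L) {
  stopifnot(inherits(target, "wing_spectrum"))
  v <- registry$values
  if (is.null(bounds)) {
    bounds <- list(h_de = v$h_de + c(-1, 1) * registry$sd[["h_de"]],
                   h_m = v$h_m + c(-1, 1) * registry$sd[["h_m"]],
                   h_ve = v$h_ve + c(-1, 1) * registry$sd[["h_ve"]])
  }
  for (nm in c("h_de", "h_m", "h_ve")) {
    b <- bounds[[nm]]
    if (is.null(b) || length(b) != 2L || b[1L] > b[2L] || b[1L] <= 0) {
      stop_invalid("`bounds$%s` must be c(lower, upper) with 0 < lower <= upper",
                   nm)
    }
  }
  wl <- target$wavelength_nm
  objective <- function(p) {
    reg <- registry
    reg$values$h_de <- p[1L]
    reg$values$h_m <- p[2L]
    reg$values$h_ve <- p[3L]
    mod <- build_membrane("three-layer", nipples, reg)
    sum((tmm_spectrum(mod$stack, wl)$reflectance$value - target$value)^2)
  }
  res_default <- objective(c(v$h_de, v$h_m, v$h_ve))
  grids <- lapply(c("h_de", "h_m", "h_ve"), function(nm) {
    b <- bounds[[nm]]
    if (b[1L] == b[2L]) b[1L] else seq(b[1L], b[2L], length.out = n_grid)
  })
  cand <- as.matrix(expand.grid(grids[[1L]], grids[[2L]], grids[[3L]]))
  vals <- apply(cand, 1L, objective)
  start <- cand[which.min(vals), ]
  lower <- vapply(bounds, `[`, numeric(1), 1L)
  upper <- vapply(bounds, `[`, numeric(1), 2L)
  if (all(lower == upper)) {
    fit <- list(par = lower, value = objective(lower))
  } else {
    fit <- optim(start, objective, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(factr = 1e4))
  }
  list(h_de = unname(fit$par[1L]), h_m = unname(fit$par[2L]),
       h_ve = unname(fit$par[3L]), residual = fit$value,
       residual_at_defaults = res_default)
}
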