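#' Read an optical stack from a YAML definition
#'
#' The YAML schema mirrors the structure files shipped under
#' `inst/extdata/models/`:
#'
#' ```yaml
#' name: membrane-three-layer
#' materials:
#'   chitin: {"n": 1.56, k: 0.0}
#'   pigment: {"n": 1.74, k: 0.010}
#' ambient: air
#' substrate: air
#' layers:
#'   - {material: chitin, thickness_nm: 436}
#'   - {material: pigment, thickness_nm: 194}
#'   - {material: chitin, thickness_nm: 412}
#' ```
#'
#' `air` (n = 1, k = 0) is predefined and need not be declared. A
#' material's `k` may also be a table,
#' `k: {wavelength_nm: [...], value: [...]}`.
#'
#' @param path YAML file path.
#' @return An [optical_stack()].
#' @export
read_stack_yaml <- function(path) {
  if (!file.exists(path)) stop_invalid("stack file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  mats <- list(air = material_air())
  for (nm in names(cfg$materials)) {
    m <- cfg$materials[[nm]]
    # YAML 1.1 reads a bare `n` key as the boolean FALSE; accept both
    if (is.null(m$n) && "FALSE" %in% names(m)) m$n <- m[["FALSE"]]
    k <- m$k
    if (is.null(k)) k <- 0
    if (is.list(k)) {
      k <- data.frame(wavelength_nm = as.numeric(k$wavelength_nm),
                      value = as.numeric(k$value))
    }
    mats[[nm]] <- optical_material(nm, m$n, k)
  }
  pick <- function(name, role) {
    if (is.null(name)) name <- "air"
    if (is.null(mats[[name]])) {
      stop_invalid("%s: %s material '%s' is not defined", path, role, name)
    }
    mats[[name]]
  }
  layers <- lapply(cfg$layers, function(ly) {
    layer(pick(ly$material, "layer"), ly$thickness_nm)
  })
  optical_stack(layers, ambient = pick(cfg$ambient, "ambient"),
                substrate = pick(cfg$substrate, "substrate"))
}
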