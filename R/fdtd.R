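#' Describe a rasterizable 2D structure for the FDTD solver
#'
#' A structure is one lateral period of a (possibly corrugated) film
#' system suspended in air, described by primitive elements stacked along
#' the propagation axis `z` (nm, `z = 0` at the illuminated face,
#' increasing into the structure). Elements are painted in order, later
#' elements overriding earlier ones:
#'
#' * `fdtd_slab(z0, z1, material)` -- a homogeneous slab spanning
#'   `[z0, z1)` across the whole period;
#' * `fdtd_nipple_row(z_tip, height_nm, diameter_nm, material, pointing)`
#'   -- one half-ellipse protuberance per period, centred laterally;
#'   `pointing = "up"` has the tip at `z_tip` facing the source and the
#'   base at `z_tip + height_nm`; `"down"` is mirrored.
#'
#' @param period_nm Lateral period (one unit cell) in nm.
#' @param elements List of elements from [fdtd_slab()] /
#'   [fdtd_nipple_row()].
#' @param name Label carried into provenance.
#' @return An object of class `fdtd_structure`.
#' @export
fdtd_structure <- function(period_nm, elements = list(), name = "structure") {
  check_number(period_nm, "period_nm")
  if (period_nm <= 0) stop_invalid("`period_nm` must be > 0")
  depth <- 0
  for (el in elements) {
    if (!inherits(el, "fdtd_element")) {
      stop_invalid("all elements must be fdtd_slab() or fdtd_nipple_row()")
    }
    depth <- max(depth, el$z1)
  }
  structure(list(period_nm = period_nm, elements = elements,
                 depth_nm = depth, name = name),
            class = "fdtd_structure")
}

#' @rdname fdtd_structure
#' @param z0,z1 Slab extent along the propagation axis, `0 <= z0 < z1`.
#' @param material An [optical_material()].
#' @export
fdtd_slab <- function(z0, z1, material) {
  check_number(z0, "z0", lower = 0)
  check_number(z1, "z1")
  if (z1 <= z0) stop_invalid("need z1 > z0")
  stopifnot(inherits(material, "optical_material"))
  structure(list(type = "slab", z0 = z0, z1 = z1, material = material),
            class = "fdtd_element")
}

#' @rdname fdtd_structure
#' @param z_tip `z` of the nipple tip in nm.
#' @param height_nm,diameter_nm Half-ellipse height and basal diameter.
#' @param pointing `"up"` (tip towards the source) or `"down"`.
#' @export
fdtd_nipple_row <- function(z_tip, height_nm, diameter_nm,
                            material = material_chitin(),
                            pointing = c("up", "down")) {
  pointing <- match.arg(pointing)
  check_number(z_tip, "z_tip", lower = 0)
  check_number(height_nm, "height_nm")
  check_number(diameter_nm, "diameter_nm")
  if (height_nm <= 0 || diameter_nm <= 0) {
    stop_invalid("nipple dimensions must be > 0")
  }
  stopifnot(inherits(material, "optical_material"))
  structure(list(type = "nipple_row", z0 = z_tip, z1 = z_tip + height_nm,
                 height_nm = height_nm, diameter_nm = diameter_nm,
                 material = material, pointing = pointing),
            class = "fdtd_element")
}

# Rasterize one period onto cell centres (i + 1/2) dx, (j + 1/2) dx within
# the structure block. Returns complex refractive index matrix (nx rows =
# lateral, ncol = structure depth cells). Structure coordinates are
# half-open intervals in nm.
rasterize_structure <- function(struct, dx, wavelength_ref) {
  nx <- max(1L, as.integer(round(struct$period_nm / dx)))
  nz <- as.integer(ceiling(struct$depth_nm / dx - 1e-9))
  xc <- (seq_len(nx) - 0.5) * dx
  zc <- (seq_len(max(nz, 1L)) - 0.5) * dx
  nmap <- matrix(1 + 0i, nrow = nx, ncol = max(nz, 1L))
  if (nz == 0L) return(nmap[, 0, drop = FALSE])
  cx <- struct$period_nm / 2
  for (el in struct$elements) {
    nv <- material_index(el$material, wavelength_ref)
    if (el$type == "slab") {
      cols <- which(zc >= el$z0 & zc < el$z1)
      if (length(cols)) nmap[, cols] <- nv
    } else {
      for (j in seq_len(nz)) {
        z <- zc[j]
        if (z < el$z0 || z >= el$z1) next
        # distance from the base plane, 0 at base, height at tip
        a <- if (el$pointing == "up") el$z1 - z else z - el$z0
        hw <- el$diameter_nm / 2 *
          sqrt(max(0, 1 - (a / el$height_nm)^2))
        inside <- abs(xc - cx) <= hw
        nmap[inside, j] <- nv
      }
    }
  }
  nmap
}

# Vertical layout of the simulation domain (cell row indices, 0-based for
# the C++ core). Margins are in cells.
fdtd_layout <- function(n_struct_cells, npml = 12L, gap_edge = 20L,
                        gap_monitor = 8L, gap_source = 60L) {
  j_refl <- npml + gap_edge
  j_src <- j_refl + gap_monitor
  j_struct0 <- j_src + gap_source
  j_tran <- j_struct0 + n_struct_cells + gap_source
  ny <- j_tran + gap_edge + npml + 1L
  list(npml = as.integer(npml), j_refl = as.integer(j_refl),
       j_src = as.integer(j_src), j_struct0 = as.integer(j_struct0),
       j_tran = as.integer(j_tran), ny = as.integer(ny))
}

# eps/sigma matrices (nx x ny) for the full domain from a structure raster.
# sigma is matched to the extinction coefficient at `wavelength_ref`.
fdtd_fill_domain <- function(nmap, layout, wavelength_ref) {
  nx <- nrow(nmap)
  ny <- layout$ny
  epsr <- matrix(1, nx, ny)
  sigma <- matrix(0, nx, ny)
  nz <- ncol(nmap)
  if (nz > 0L) {
    cols <- layout$j_struct0 + seq_len(nz) # 1-based R columns: j (0-based) + 1
    n_re <- Re(nmap)
    n_im <- Im(nmap)
    epsr[, cols] <- n_re^2 - n_im^2
    omega <- 2 * pi / wavelength_ref
    sigma[, cols] <- 2 * n_re * n_im * omega
  }
  list(epsr = epsr, sigma = sigma)
}

check_fdtd_resolution <- function(dx, band, n_max) {
  lam_min <- min(band)
  if (dx > lam_min / (20 * n_max) + 1e-9) {
    stop_invalid(
      "dx = %g nm is too coarse: need dx <= lambda_min / (20 n_max) = %g nm",
      dx, lam_min / (20 * n_max))
  }
}

gaussian_pulse <- function(band, dt) {
  f_lo <- 1 / max(band)
  f_hi <- 1 / min(band)
  f0 <- (f_lo + f_hi) / 2
  sd_f <- (f_hi - f_lo) / 2
  tau <- 1 / (pi * sd_f)
  t0 <- 4.5 * tau
  n_src <- as.integer(ceiling(2 * t0 / dt))
  t <- (seq_len(n_src)) * dt
  exp(-((t - t0) / tau)^2) * sin(2 * pi * f0 * (t - t0))
}

monitor_flux <- function(E, H, sign = 1) {
  # E, H: complex matrices (n_lambda x nx); downward power flux per lambda
  sign * 0.5 * rowSums(Re(E * Conj(H)))
}

#' Run a broadband 2D FDTD reflectance/transmittance simulation
#'
#' Propagates a normally incident broadband plane-wave pulse through one
#' lateral period of `structure` (periodic lateral boundaries, CPML
#' absorbers along the propagation axis) and extracts reflectance and
#' transmittance spectra from running discrete Fourier transforms at
#' power-flux monitor lines. The reflected wave is isolated by subtracting
#' the fields of an empty-domain reference run (which also provides the
#' incident-power normalization), so each spectrum costs two time-domain
#' runs.
#'
#' Absorbing media enter through an electrical conductivity matched to
#' their extinction coefficient at the band centre. The run fails with an
#' explicit simulation error if the field energy has not decayed below
#' `decay_tol` of its peak within `max_steps` (never by silent
#' truncation).
#'
#' @param structure An [fdtd_structure()].
#' @param band Wavelength grid in nm (strictly increasing, within
#'   350--950 nm).
#' @param dx_nm Spatial step in nm (default 5). Must satisfy
#'   `dx <= lambda_min / (20 n_max)`.
#' @param polarization `"TM"` (E out of plane, default) or `"TE"`.
#' @param courant Courant factor `dt = courant * dx` (must be `< 1/sqrt(2)`).
#' @param npml CPML thickness in cells (>= 10).
#' @param max_steps,decay_tol Termination controls for the pulsed run.
#' @return List with `reflectance` and `transmittance` [spectrum()]s plus
#'   a `diagnostics` list (steps used, energy decay ratio, grid size).
#' @export
run_fdtd_spectrum <- function(structure, band = seq(400, 700, by = 2),
                              dx_nm = 5, polarization = c("TM", "TE"),
                              courant = 0.5, npml = 30L,
                              max_steps = 200000L, decay_tol = 1e-7) {
  polarization <- match.arg(polarization)
  stopifnot(inherits(structure, "fdtd_structure"))
  check_wavelengths(band, "band")
  if (min(band) < 350 || max(band) > 950) {
    stop_invalid("band must lie within [350, 950] nm")
  }
  if (length(band) < 2L) stop_invalid("band needs at least 2 wavelengths")
  if (courant >= 1 / sqrt(2)) {
    stop_invalid("courant = %g violates the 2D stability bound 1/sqrt(2)",
                 courant)
  }
  if (npml < 10L) stop_invalid("npml must be >= 10 cells")
  lam_ref <- 2 / (1 / min(band) + 1 / max(band))
  nmap <- rasterize_structure(structure, dx_nm, lam_ref)
  check_fdtd_resolution(dx_nm, band, max(Mod(nmap), 1))
  layout <- fdtd_layout(ncol(nmap), npml)
  dom <- fdtd_fill_domain(nmap, layout, lam_ref)
  empty <- list(epsr = matrix(1, nrow(dom$epsr), ncol(dom$epsr)),
                sigma = matrix(0, nrow(dom$epsr), ncol(dom$epsr)))
  dt <- courant * dx_nm
  src <- gaussian_pulse(band, dt)
  omegas <- 2 * pi / band
  core <- if (polarization == "TM") fdtd_pulse_tm_cpp else fdtd_pulse_te_cpp
  flux_sign <- if (polarization == "TM") 1 else -1

  run1 <- core(empty$epsr, empty$sigma, dx_nm, dt, layout$npml, layout$j_src,
               layout$j_refl, layout$j_tran, src, omegas,
               as.integer(max_steps), decay_tol, 500L)
  run2 <- core(dom$epsr, dom$sigma, dx_nm, dt, layout$npml, layout$j_src,
               layout$j_refl, layout$j_tran, src, omegas,
               as.integer(max_steps), decay_tol, 500L)
  for (rn in list(run1, run2)) {
    if (!rn$decayed) {
      stop_invalid(
        "FDTD simulation failure: field energy did not decay below %g of peak within %d steps (ratio %.3g)",
        decay_tol, max_steps, rn$energy_ratio)
    }
  }
  p_inc <- monitor_flux(run1$Et, run1$Ht, flux_sign)
  if (any(p_inc <= 0)) {
    stop_invalid("FDTD simulation failure: non-positive incident power at a band wavelength")
  }
  Es <- run2$Er - run1$Er
  Hs <- run2$Hr - run1$Hr
  p_refl <- -monitor_flux(Es, Hs, flux_sign) # reflected flux travels upward
  p_tran <- monitor_flux(run2$Et, run2$Ht, flux_sign)
  R <- pmin(pmax(p_refl / p_inc, 0), 1)
  Tt <- pmin(pmax(p_tran / p_inc, 0), 1)
  prov <- list(method = "fdtd2d", polarization = polarization,
               structure = structure$name, dx_nm = dx_nm)
  list(reflectance = spectrum(band, R, "reflectance", prov),
       transmittance = spectrum(band, Tt, "transmittance", prov),
       diagnostics = list(steps = c(run1$steps, run2$steps),
                          energy_ratio = c(run1$energy_ratio,
                                           run2$energy_ratio),
                          nx = nrow(dom$epsr), ny = ncol(dom$epsr),
                          dt = dt, lambda_ref = lam_ref))
}

#' Steady-state field map at a single wavelength
#'
#' Runs a continuous-wave (ramped sinusoid) TM simulation to steady state
#' and returns the complex field amplitude over the whole domain,
#' normalized to unit incident amplitude (taken from an identical
#' empty-domain run). The spatially averaged magnitude of the
#' *scattered* (total minus incident) field along the monitor line in the
#' reflected-field region above the source equals `sqrt(R)` at that
#' wavelength for a clean back-propagating wave, and is reported as
#' `reflected_magnitude`.
#'
#' Steady state is verified by comparing two consecutive accumulation
#' blocks; disagreement beyond `steady_tol` raises a simulation error.
#'
#' @inheritParams run_fdtd_spectrum
#' @param wavelength_nm Single wavelength in nm.
#' @param n_ramp_periods,n_settle_periods,n_block_periods CW timing
#'   controls, in optical periods.
#' @param steady_tol Maximum relative disagreement between accumulation
#'   blocks.
#' @return An object of class `field_map`: list with `wavelength_nm`,
#'   `magnitude` (nx-by-ny matrix, incident-normalized; for TE the
#'   in-plane electric-field vector magnitude), `x_nm`, `y_nm`,
#'   `monitors` (row indices), `reflected_magnitude` and
#'   `transmitted_magnitude`.
#' @export
steady_state_field <- function(structure, wavelength_nm, dx_nm = 5,
                               polarization = c("TM", "TE"),
                               courant = 0.5, npml = 30L,
                               n_ramp_periods = 15, n_settle_periods = 60,
                               n_block_periods = 12, steady_tol = 0.01) {
  polarization <- match.arg(polarization)
  stopifnot(inherits(structure, "fdtd_structure"))
  check_number(wavelength_nm, "wavelength_nm", lower = 350, upper = 950)
  nmap <- rasterize_structure(structure, dx_nm, wavelength_nm)
  check_fdtd_resolution(dx_nm, c(wavelength_nm, wavelength_nm),
                        max(Mod(nmap), 1))
  layout <- fdtd_layout(ncol(nmap), npml)
  dom <- fdtd_fill_domain(nmap, layout, wavelength_nm)
  empty <- list(epsr = matrix(1, nrow(dom$epsr), ncol(dom$epsr)),
                sigma = matrix(0, nrow(dom$epsr), ncol(dom$epsr)))
  dt <- courant * dx_nm
  period <- wavelength_nm # c = 1
  steps_per_period <- period / dt
  n_settle <- as.integer(ceiling(n_settle_periods * steps_per_period))
  n_block <- as.integer(ceiling(n_block_periods * steps_per_period))
  omega <- 2 * pi / wavelength_nm
  t <- seq_len(n_settle + 2L * n_block) * dt
  ramp <- 1 - exp(-(t / (n_ramp_periods * period))^2)
  src <- ramp * sin(omega * t)

  core <- if (polarization == "TM") fdtd_cw_tm_cpp else fdtd_cw_te_cpp
  cw <- function(d) core(d$epsr, d$sigma, dx_nm, dt, layout$npml,
                         layout$j_src, layout$j_refl, layout$j_tran,
                         src, omega, n_settle, n_block)
  ref <- cw(empty)
  run <- cw(dom)
  jr <- layout$j_refl + 1L # 1-based column
  jt <- layout$j_tran + 1L
  if (max(Mod(ref$map1)) <= 0) {
    stop_invalid("FDTD simulation failure: zero field (reference)")
  }
  # Steady state is judged on the reported monitor observables: near
  # high-Q guided resonances the field deep inside the structure keeps
  # ringing up long after the radiated (monitored) amplitudes have
  # settled, so a whole-map criterion would be needlessly conservative.
  obs <- function(run_map, ref_map) {
    a_inc <- mean(Mod(ref_map[, jr]))
    c(refl = mean(Mod(run_map[, jr] - ref_map[, jr])) / a_inc,
      tran = mean(Mod(run_map[, jt])) / a_inc)
  }
  o1 <- obs(run$map1, ref$map1)
  o2 <- obs(run$map2, ref$map2)
  rel <- max(abs(o2 - o1)) / max(max(abs(o1)), 0.05)
  if (rel > steady_tol) {
    stop_invalid(
      "FDTD simulation failure: CW run not at steady state (monitor block disagreement %.3g > %g; increase n_settle_periods)",
      rel, steady_tol)
  }
  amp_ref <- (ref$map1 + ref$map2) / 2
  amp_run <- (run$map1 + run$map2) / 2
  a_inc <- mean(Mod(amp_ref[, jr]))
  refl_mag <- mean(Mod(amp_run[, jr] - amp_ref[, jr])) / a_inc
  tran_mag <- mean(Mod(amp_run[, jt])) / a_inc
  nx <- nrow(amp_run)
  mag <- Mod(amp_run)
  if (polarization == "TE") {
    # add the (generally small) Ey component, averaged onto Ex locations
    ey <- (run$ey1 + run$ey2) / 2
    ey_c <- matrix(0, nrow(amp_run), ncol(amp_run))
    ip <- c(seq_len(nx)[-1L], 1L)
    inner <- 2:(ncol(amp_run) - 1L)
    ey_c[, inner] <- (Mod(ey[, inner - 1L]) + Mod(ey[, inner]) +
                        Mod(ey[ip, inner - 1L]) + Mod(ey[ip, inner])) / 4
    mag <- sqrt(mag^2 + ey_c^2)
  }
  ny <- ncol(amp_run)
  structure(list(wavelength_nm = wavelength_nm,
                 magnitude = mag / a_inc,
                 x_nm = (seq_len(nx) - 0.5) * dx_nm,
                 y_nm = (seq_len(ny) - 0.5) * dx_nm,
                 monitors = list(source_row = layout$j_src + 1L,
                                 reflected_row = jr, transmitted_row = jt,
                                 structure_rows = layout$j_struct0 + 1L +
                                   c(0L, max(ncol(nmap) - 1L, 0L))),
                 reflected_magnitude = refl_mag,
                 transmitted_magnitude = tran_mag),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf(
    "<field_map> %g nm, %d x %d cells; reflected |E| = %.3f, transmitted |E| = %.3f\n",
    x$wavelength_nm, nrow(x$magnitude), ncol(x$magnitude),
    x$reflected_magnitude, x$transmitted_magnitude))
  invisible(x)
}

#' Write a field map as a CSV matrix
#'
#' @param fm A [steady_state_field()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_map_csv <- function(fm, path) {
  stopifnot(inherits(fm, "field_map"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# field magnitude at %g nm, rows = lateral x, cols = propagation y",
                     fm$wavelength_nm), con)
  write.csv(as.data.frame(fm$magnitude), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
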