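#' Run the wing-membrane transparency analysis
#'
#' End-to-end membrane study: builds the one-layer, three-layer and
#' three-layer-with-nipples membrane models, computes their
#' reflectance/transmittance spectra (transfer matrix always; FDTD for the
#' corrugated model when requested), summarizes the bimodal reflectance
#' extrema, checks the visible-band transparency bound, and -- when FDTD
#' is enabled -- records steady-state reflected-field magnitudes at the
#' spectral extrema together with their `sqrt(R)` cross-check.
#'
#' @param method `"tmm"`, `"fdtd"` or `"both"` (default `"tmm"`; FDTD adds
#'   the full-wave simulation of the nippled membrane).
#' @param band Wavelength grid in nm for the spectra.
#' @param nipples Nipple placement for the corrugated model (`"dorsal"` or
#'   `"both"`).
#' @param registry A [param_registry()].
#' @param dx_nm FDTD spatial step.
#' @param fdtd_polarization Polarization for the corrugated-membrane FDTD
#'   runs. Default `"TE"` (E in the plane, across the nipple rows): in the
#'   2D reduction of the polarization-isotropic nipple array, the TE
#'   response of the half-ellipse ridge row is the closer surrogate for
#'   the dilute three-dimensional array, whereas TM (E along the ridges)
#'   overweights the corrugation.
#' @param out_dir Optional directory; when given, spectra and the extrema
#'   table are written as CSV files.
#' @return A list report: `spectra` (per model, per method), `extrema`
#'   (bimodal summary of the three-layer model), `transparency`
#'   (min/mean visible transmittance of the nippled model and the > 0.80
#'   verdict), `one_layer_flag`, `fields` (FDTD only), `config`.
#' @export
run_membrane_analysis <- function(method = c("tmm", "fdtd", "both"),
                                  band = seq(400, 700, by = 1),
                                  nipples = "dorsal",
                                  registry = param_registry(), dx_nm = 5,
                                  fdtd_polarization = "TE",
                                  out_dir = NULL) {
  method <- match.arg(method)
  models <- list(
    one_layer = build_membrane("one-layer", "none", registry),
    three_layer = build_membrane("three-layer", "none", registry),
    three_layer_nipples = build_membrane("three-layer", nipples, registry))
  spectra <- lapply(models, function(m) list(tmm = tmm_spectrum(m$stack, band)))

  extrema <- bimodal_summary(spectra$three_layer$tmm$reflectance)
  pk_one <- prominent_maxima(spectra$one_layer$tmm$reflectance)
  pk_three <- prominent_maxima(spectra$three_layer$tmm$reflectance)
  one_layer_flag <- if (nrow(pk_one) > nrow(pk_three)) {
    sprintf("multiple peaks (%d prominent maxima vs %d for the three-layer model)",
            nrow(pk_one), nrow(pk_three))
  } else {
    "prominent-peak count not above the three-layer model"
  }

  fields <- NULL
  if (method %in% c("fdtd", "both")) {
    fband <- if (length(band) > 151L) {
      seq(min(band), max(band), length.out = 151L)
    } else {
      band
    }
    fd <- run_fdtd_spectrum(models$three_layer_nipples$structure, fband,
                            dx_nm = dx_nm,
                            polarization = fdtd_polarization)
    spectra$three_layer_nipples$fdtd <- fd
    # despike: the periodic unit cell carries narrow guided-mode
    # resonances the disordered real array does not (see vignette)
    summ <- bimodal_summary(despike_spectrum(fd$reflectance))
    eval_at <- c(short_peak = summ$peaks$wavelength_nm[1L],
                 dip = if (!is.null(summ$dip)) summ$dip$wavelength_nm else NA,
                 long_peak = summ$peaks$wavelength_nm[2L])
    fields <- lapply(eval_at[is.finite(eval_at)], function(wl) {
      # long settle: guided resonances of the periodic nipple row ring up
      # slowly, and the monitored amplitudes must be converged
      fm <- steady_state_field(models$three_layer_nipples$structure, wl,
                               dx_nm = dx_nm,
                               polarization = fdtd_polarization,
                               n_settle_periods = 400, n_block_periods = 20)
      r_at <- approx(fd$reflectance$wavelength_nm, fd$reflectance$value,
                     xout = wl)$y
      list(wavelength_nm = wl, reflected_magnitude = fm$reflected_magnitude,
           sqrt_R = sqrt(r_at),
           cross_check_abs_diff = abs(fm$reflected_magnitude - sqrt(r_at)))
    })
  }

  trans_spec <- if (!is.null(spectra$three_layer_nipples$fdtd)) {
    spectra$three_layer_nipples$fdtd$transmittance
  } else {
    spectra$three_layer_nipples$tmm$transmittance
  }
  vis <- c(max(400, min(band)), min(700, max(band)))
  transparency <- list(
    band_nm = vis,
    min_T = band_stat(trans_spec, vis, "min"),
    mean_T = band_stat(trans_spec, vis, "mean"),
    exceeds_080 = band_stat(trans_spec, vis, "min") > 0.80,
    method = if (!is.null(spectra$three_layer_nipples$fdtd)) "fdtd" else "tmm")

  report <- list(spectra = spectra, extrema = extrema,
                 one_layer_flag = one_layer_flag,
                 transparency = transparency, fields = fields,
                 config = list(method = method, band = range(band),
                               nipples = nipples, dx_nm = dx_nm,
                               registry = registry))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(spectra)) {
      for (meth in names(spectra[[nm]])) {
        write_spectrum_csv(spectra[[nm]][[meth]]$reflectance,
                           file.path(out_dir, sprintf("%s_%s_R.csv", nm, meth)))
        write_spectrum_csv(spectra[[nm]][[meth]]$transmittance,
                           file.path(out_dir, sprintf("%s_%s_T.csv", nm, meth)))
      }
    }
    ext_tab <- rbind(cbind(extrema$peaks, role = "peak"),
                     if (!is.null(extrema$dip)) cbind(extrema$dip,
                                                      role = "dip"))
    write.csv(ext_tab, file.path(out_dir, "membrane_extrema.csv"),
              row.names = FALSE, quote = FALSE)
  }
  report
}

#' Run the scale structural-color analysis
#'
#' Computes the interridge reflectance spectrum and its single prominent
#' peak, sweeps the microrib spacing to verify the blue-shift, and -- when
#' the (unmeasured, therefore required) ridge geometry is supplied --
#' evaluates the ridge multilayer model. Without `h_air_nm` and
#' `lamella_nm` the ridge stage is skipped with a notice rather than a
#' silent default.
#'
#' @param h_air_nm,lamella_nm Ridge air-gap and lamella thicknesses in nm
#'   (optional; both required for the ridge stage to run).
#' @param gaps_nm Microrib gaps for the spacing sweep.
#' @param band Wavelength band for all spectra.
#' @param registry A [param_registry()].
#' @param out_dir Optional CSV output directory.
#' @return A list report: `interridge` (spectrum + peak), `sweep`
#'   (gap/peak table), `ridge` (spectrum + peak, or `"not run"` notice),
#'   `config`.
#' @export
run_scale_analysis <- function(h_air_nm = NULL, lamella_nm = NULL,
                               gaps_nm = c(40, 58, 80, 120),
                               band = c(400, 700),
                               registry = param_registry(), out_dir = NULL) {
  wl <- seq(band[1L], band[2L], by = 1)
  inter <- tmm_spectrum(build_interridge(registry), wl)
  ext <- find_extrema(inter$reflectance)
  maxima <- ext[ext$type == "max", , drop = FALSE]
  inter_peak <- if (nrow(maxima)) {
    maxima$wavelength_nm[which.max(maxima$prominence)]
  } else {
    NA_real_
  }
  sweep <- microrib_spacing_sweep(gaps_nm, registry, band)

  ridge <- if (is.null(h_air_nm) || is.null(lamella_nm)) {
    message("ridge stage not run: supply both `h_air_nm` and `lamella_nm` (no measured defaults exist)")
    list(status = "not run",
         reason = "h_air_nm and lamella_nm are required inputs")
  } else {
    rs <- tmm_spectrum(build_ridge(h_air_nm, lamella_nm, registry), wl)
    rext <- find_extrema(rs$reflectance)
    rmax <- rext[rext$type == "max", , drop = FALSE]
    list(status = "run", spectra = rs,
         peak_nm = if (nrow(rmax)) {
           rmax$wavelength_nm[which.max(rmax$prominence)]
         } else {
           NA_real_
         },
         h_air_nm = h_air_nm, lamella_nm = lamella_nm)
  }

  report <- list(interridge = list(spectra = inter, peak_nm = inter_peak),
                 sweep = sweep, ridge = ridge,
                 config = list(band = band, gaps_nm = gaps_nm,
                               registry = registry))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_spectrum_csv(inter$reflectance,
                       file.path(out_dir, "interridge_R.csv"))
    write.csv(sweep, file.path(out_dir, "microrib_sweep.csv"),
              row.names = FALSE, quote = FALSE)
    if (identical(ridge$status, "run")) {
      write_spectrum_csv(ridge$spectra$reflectance,
                         file.path(out_dir, "ridge_R.csv"))
    }
  }
  report
}

#' Run the wettability analysis
#'
#' Extracts static contact angles per wing region and compares the
#' groups. Input is either a named list of contour sources (file paths or
#' [droplet_contour()] objects, grouped by region), or -- by default --
#' synthetic goniometry: per-region droplet angles are drawn from normal
#' distributions whose defaults emulate the three study conditions (black
#' scales 145 +/- 3.2, transparent region 114 +/- 6.9, scale-brushed
#' membrane 93 +/- 11.1 degrees, five droplets each), synthesized as
#' noisy circular-cap contours and re-extracted with [contact_angle()].
#'
#' @param contours Optional named list: `region -> list of contour
#'   sources`. When `NULL`, synthetic mode is used and `seed` is
#'   required.
#' @param seed Integer seed for synthetic mode.
#' @param group_means,group_sds Named numeric vectors defining synthetic
#'   regions (degrees).
#' @param n_per_group Synthetic droplets per region (default 5).
#' @param noise_frac Contour coordinate noise for synthetic droplets
#'   (default 0.005).
#' @param paired Passed to [compare_groups()] for consecutive region
#'   pairs.
#' @param out_dir Optional CSV output directory.
#' @return A list report: `angles` (tidy data frame: region, droplet,
#'   angle, classification), `group_stats`, `comparisons` (pairwise
#'   t-tests between consecutive regions), `ordering`, `config`.
#' @export
run_wettability_analysis <- function(contours = NULL, seed = NULL,
                                     group_means = c(black = 145,
                                                     transparent = 114,
                                                     membrane = 93),
                                     group_sds = c(black = 3.2,
                                                   transparent = 6.9,
                                                   membrane = 11.1),
                                     n_per_group = 5L, noise_frac = 0.005,
                                     paired = TRUE, out_dir = NULL) {
  if (is.null(contours)) {
    stopifnot(length(group_means) == length(group_sds),
              !is.null(names(group_means)))
    true_angles <- with_local_seed(seed, {
      lapply(seq_along(group_means), function(g) {
        pmin(pmax(rnorm(n_per_group, group_means[[g]], group_sds[[g]]),
                  5), 175)
      })
    })
    names(true_angles) <- names(group_means)
    contours <- lapply(seq_along(true_angles), function(g) {
      lapply(seq_len(n_per_group), function(i) {
        synth_droplet_contour(true_angles[[g]][i], radius = 1,
                              n_points = 181L,
                              seed = seed + 1000L * g + i,
                              noise_frac = noise_frac)
      })
    })
    names(contours) <- names(true_angles)
  } else {
    contours <- lapply(contours, function(group) {
      lapply(group, function(src) {
        if (inherits(src, "droplet_contour")) return(src)
        read_contour_csv(src)
      })
    })
  }

  rows <- list()
  for (region in names(contours)) {
    for (i in seq_along(contours[[region]])) {
      res <- contact_angle(contours[[region]][[i]])
      rows[[length(rows) + 1L]] <- data.frame(
        region = region, droplet = i, theta_deg = res$theta_mean_deg,
        residual_rms = res$residual_rms,
        classification = classify_wettability(res$theta_mean_deg))
    }
  }
  angles <- do.call(rbind, rows)

  group_stats <- do.call(rbind, lapply(split(angles, angles$region), function(d) {
    data.frame(region = d$region[1L], n = nrow(d), mean_deg = mean(d$theta_deg),
               sd_deg = sd(d$theta_deg))
  }))
  group_stats <- group_stats[match(names(contours), group_stats$region), ]
  rownames(group_stats) <- NULL

  comparisons <- NULL
  if (length(contours) >= 2L) {
    regs <- names(contours)
    comparisons <- lapply(seq_len(length(regs) - 1L), function(i) {
      a <- angles$theta_deg[angles$region == regs[i]]
      b <- angles$theta_deg[angles$region == regs[i + 1L]]
      cg <- if (paired && length(a) == length(b)) {
        compare_groups(a, b, paired = TRUE)
      } else {
        compare_groups(a, b, paired = FALSE)
      }
      c(list(groups = paste(regs[i], "vs", regs[i + 1L])), cg)
    })
  }
  ordering <- paste(group_stats$region[order(-group_stats$mean_deg)],
                    collapse = " > ")

  report <- list(angles = angles, group_stats = group_stats,
                 comparisons = comparisons, ordering = ordering,
                 config = list(synthetic = is.null(rows$file),
                               seed = seed, n_per_group = n_per_group,
                               group_means = group_means,
                               group_sds = group_sds, paired = paired))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(angles, file.path(out_dir, "contact_angles.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(group_stats, file.path(out_dir, "group_stats.csv"),
              row.names = FALSE, quote = FALSE)
  }
  report
}
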