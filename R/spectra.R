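#' Construct a spectrum
#'
#' The spectrum is the universal currency between modelling stages: a
#' strictly increasing wavelength grid paired with an optical quantity.
#' Reflectance and transmittance are validated to lie in `[0, 1]` (with a
#' 1e-9 numerical allowance); absorbance and field magnitudes must be
#' non-negative.
#'
#' @param wavelength_nm Strictly increasing wavelength grid (nm), at least
#'   two points.
#' @param value Numeric values, one per wavelength.
#' @param kind One of `"reflectance"`, `"transmittance"`, `"absorbance"`,
#'   `"field-magnitude"`.
#' @param provenance Optional free-form list recording how the spectrum was
#'   produced (model name, method, replicate count, ...).
#' @return A `data.frame` of class `wing_spectrum` with columns
#'   `wavelength_nm` and `value`.
#' @export
spectrum <- function(wavelength_nm, value,
                     kind = c("reflectance", "transmittance", "absorbance",
                              "field-magnitude"),
                     provenance = list()) {
  kind <- match.arg(kind)
  check_wavelengths(wavelength_nm)
  if (length(wavelength_nm) < 2L) {
    stop_invalid("a spectrum needs at least 2 wavelength points")
  }
  if (length(value) != length(wavelength_nm)) {
    stop_invalid("`value` and `wavelength_nm` lengths differ")
  }
  if (!is.numeric(value) || any(!is.finite(value))) {
    stop_invalid("spectrum values must be finite")
  }
  tol <- 1e-9
  if (kind %in% c("reflectance", "transmittance")) {
    if (any(value < -tol) || any(value > 1 + tol)) {
      stop_invalid("%s values must lie in [0, 1]", kind)
    }
  } else if (any(value < -tol)) {
    stop_invalid("%s values must be >= 0", kind)
  }
  out <- data.frame(wavelength_nm = as.numeric(wavelength_nm),
                    value = as.numeric(value))
  attr(out, "kind") <- kind
  attr(out, "provenance") <- provenance
  class(out) <- c("wing_spectrum", "data.frame")
  out
}

#' @export
print.wing_spectrum <- function(x, ...) {
  cat(sprintf("<wing_spectrum> %s, %d points over [%g, %g] nm\n",
              attr(x, "kind"), nrow(x), min(x$wavelength_nm),
              max(x$wavelength_nm)))
  invisible(x)
}

spectrum_kind <- function(s) attr(s, "kind")

check_band <- function(s, band) {
  if (is.null(band)) band <- range(s$wavelength_nm)
  if (length(band) != 2L || !is.numeric(band) || band[1L] >= band[2L]) {
    stop_invalid("`band` must be c(min, max) with min < max")
  }
  if (band[1L] < min(s$wavelength_nm) - 1e-9 ||
      band[2L] > max(s$wavelength_nm) + 1e-9) {
    stop_invalid("band [%g, %g] nm lies outside the spectrum grid [%g, %g] nm",
                 band[1L], band[2L], min(s$wavelength_nm),
                 max(s$wavelength_nm))
  }
  band
}

moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  if (window %% 2L == 0L) stop_invalid("smoothing `window` must be odd")
  half <- (window - 1L) %/% 2L
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# Plateau-aware local extrema of a numeric series. Returns integer indices
# (plateau midpoints) and types, excluding the series endpoints.
local_extrema_idx <- function(y) {
  r <- rle(y)
  nv <- length(r$values)
  if (nv < 3L) {
    return(data.frame(index = integer(), type = character()))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- integer()
  typ <- character()
  for (j in 2:(nv - 1L)) {
    left <- r$values[j - 1L]
    mid <- r$values[j]
    right <- r$values[j + 1L]
    if (mid > left && mid > right) {
      idx <- c(idx, as.integer(round((starts[j] + ends[j]) / 2)))
      typ <- c(typ, "max")
    } else if (mid < left && mid < right) {
      idx <- c(idx, as.integer(round((starts[j] + ends[j]) / 2)))
      typ <- c(typ, "min")
    }
  }
  data.frame(index = idx, type = typ)
}

# Topographic prominence of extremum `i0` within series y. For maxima this
# is the height above the higher of the two key saddles on the way to
# higher terrain (band edges count as terrain ends); minima are handled by
# negating the series.
prominence_of <- function(y, ext, which_row) {
  i0 <- ext$index[which_row]
  v0 <- y[i0]
  sgn <- if (ext$type[which_row] == "max") 1 else -1
  z <- sgn * y
  z0 <- sgn * v0
  n <- length(z)
  # walk left
  left_min <- z0
  i <- i0
  left_base <- NA_real_
  while (i > 1L) {
    i <- i - 1L
    if (z[i] > z0) { left_base <- left_min; break }
    if (z[i] < left_min) left_min <- z[i]
  }
  if (is.na(left_base)) left_base <- left_min
  right_min <- z0
  i <- i0
  right_base <- NA_real_
  while (i < n) {
    i <- i + 1L
    if (z[i] > z0) { right_base <- right_min; break }
    if (z[i] < right_min) right_min <- z[i]
  }
  if (is.na(right_base)) right_base <- right_min
  z0 - max(left_base, right_base)
}

#' Locate local extrema of a spectrum
#'
#' Detects local maxima and minima of the (optionally smoothed) spectrum
#' within a band. Smoothing is a centered moving average applied only for
#' detection -- reported values are read from the raw spectrum at the
#' detected wavelength. Plateaus report their midpoint; band endpoints are
#' never reported as extrema; extrema with topographic prominence below
#' `prominence_min` are dropped.
#'
#' @param s A [spectrum()].
#' @param band `c(min, max)` wavelength band in nm (default: full grid).
#' @param smoothing_window Odd integer window (points) for the moving
#'   average used during detection; `1` disables smoothing. Default 5.
#' @param prominence_min Minimum absolute prominence for an extremum to be
#'   reported (default 0.005, below the FDTD accuracy floor).
#' @return `data.frame` with columns `wavelength_nm`, `value`, `type`
#'   (`"max"`/`"min"`) and `prominence`, ordered by wavelength.
#' @export
find_extrema <- function(s, band = NULL, smoothing_window = 5L,
                         prominence_min = 0.005) {
  stopifnot(inherits(s, "wing_spectrum"))
  band <- check_band(s, band)
  keep <- s$wavelength_nm >= band[1L] - 1e-9 & s$wavelength_nm <= band[2L] + 1e-9
  wl <- s$wavelength_nm[keep]
  raw <- s$value[keep]
  if (length(wl) < 3L) {
    return(data.frame(wavelength_nm = numeric(), value = numeric(),
                      type = character(), prominence = numeric()))
  }
  ys <- moving_average(raw, as.integer(smoothing_window))
  ext <- local_extrema_idx(ys)
  if (nrow(ext) == 0L) {
    return(data.frame(wavelength_nm = numeric(), value = numeric(),
                      type = character(), prominence = numeric()))
  }
  prom <- vapply(seq_len(nrow(ext)), function(r) prominence_of(ys, ext, r),
                 numeric(1))
  out <- data.frame(wavelength_nm = wl[ext$index],
                    value = raw[ext$index],
                    type = ext$type,
                    prominence = prom)
  out <- out[out$prominence >= prominence_min, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$wavelength_nm), , drop = FALSE]
}

#' Summarize a bimodal reflectance spectrum
#'
#' Reports the two most prominent local maxima in the band and the interior
#' dip between them. Thin-film spectra often carry secondary interference
#' wiggles between the two main lobes, so "the dip" is defined by the
#' central-dip convention: among the interior local minima that survive the
#' prominence filter, the one closest to the midpoint of the two peak
#' wavelengths is reported as the dip separating the lobes.
#'
#' @inheritParams find_extrema
#' @return List with `peaks` (data.frame, 2 rows, ordered by wavelength)
#'   and `dip` (1-row data.frame, or NULL when no interior minimum exists).
#' @export
bimodal_summary <- function(s, band = NULL, smoothing_window = 5L,
                            prominence_min = 0.005) {
  ext <- find_extrema(s, band, smoothing_window, prominence_min)
  maxima <- ext[ext$type == "max", , drop = FALSE]
  if (nrow(maxima) < 2L) {
    stop_invalid("spectrum has fewer than two prominent maxima in the band")
  }
  top2 <- maxima[order(-maxima$prominence)[1:2], , drop = FALSE]
  top2 <- top2[order(top2$wavelength_nm), , drop = FALSE]
  lo <- top2$wavelength_nm[1L]
  hi <- top2$wavelength_nm[2L]
  minima <- ext[ext$type == "min" & ext$wavelength_nm > lo &
                  ext$wavelength_nm < hi, , drop = FALSE]
  dip <- NULL
  if (nrow(minima) > 0L) {
    mid <- (lo + hi) / 2
    dip <- minima[which.min(abs(minima$wavelength_nm - mid)), , drop = FALSE]
  }
  list(peaks = top2, dip = dip)
}

#' Remove narrow spectral spikes by median filtering
#'
#' Coherent full-wave simulations of perfectly periodic structures carry
#' narrow guided-mode resonance spikes that the real, disordered
#' structure does not sustain. A running-median prefilter (window `k`
#' points) removes isolated spikes while leaving the broad thin-film
#' backbone untouched, so extremum analysis can address the backbone.
#'
#' @param s A [spectrum()].
#' @param k Odd median window in points (default 7).
#' @return A [spectrum()] of the same kind.
#' @export
despike_spectrum <- function(s, k = 7L) {
  stopifnot(inherits(s, "wing_spectrum"))
  v <- stats::runmed(s$value, k = as.integer(k), endrule = "median")
  spectrum(s$wavelength_nm, pmin(pmax(v, 0), max(s$value)),
           kind = attr(s, "kind"),
           provenance = c(attr(s, "provenance"), list(despiked_k = k)))
}

#' Prominent maxima of a spectrum
#'
#' Local maxima whose topographic prominence is at least `rel` times the
#' prominence of the strongest maximum in the band (the half-of-maximum
#' convention by default). This is the package's working definition of
#' "how many peaks does this spectrum have": interference wiggles riding
#' on a dominant lobe do not count, near-equal fringes all do.
#'
#' @inheritParams find_extrema
#' @param rel Relative prominence cut in (0, 1], default 0.5.
#' @return Subset of [find_extrema()] rows of type `"max"`.
#' @export
prominent_maxima <- function(s, band = NULL, smoothing_window = 5L,
                             prominence_min = 0.005, rel = 0.5) {
  ext <- find_extrema(s, band, smoothing_window, prominence_min)
  maxima <- ext[ext$type == "max", , drop = FALSE]
  if (nrow(maxima) == 0L) return(maxima)
  maxima[maxima$prominence >= rel * max(maxima$prominence), , drop = FALSE]
}

#' Band statistic of a spectrum
#'
#' `mean` is the trapezoid-weighted average over the band (so unevenly
#' sampled grids are handled correctly); `min` and `max` are taken over the
#' grid points inside the band.
#'
#' @inheritParams find_extrema
#' @param stat One of `"mean"`, `"min"`, `"max"`.
#' @return A single number.
#' @export
band_stat <- function(s, band = NULL, stat = c("mean", "min", "max")) {
  stopifnot(inherits(s, "wing_spectrum"))
  stat <- match.arg(stat)
  band <- check_band(s, band)
  keep <- s$wavelength_nm >= band[1L] - 1e-9 & s$wavelength_nm <= band[2L] + 1e-9
  wl <- s$wavelength_nm[keep]
  v <- s$value[keep]
  if (length(wl) == 0L) stop_invalid("no grid points inside the band")
  switch(stat,
         mean = if (length(wl) == 1L) v else
           pracma::trapz(wl, v) / (max(wl) - min(wl)),
         min = min(v),
         max = max(v))
}

#' Compare two spectra on their common band
#'
#' Both spectra are resampled by linear interpolation onto the coarser of
#' the two grids restricted to the overlapping band, then compared.
#' Difference metrics are symmetric in the two arguments. Extremum offsets
#' pair the extrema of `a` and `b` by type in wavelength order (as many
#' pairs as the shorter list).
#'
#' @param a,b [spectrum()] objects with overlapping wavelength bands.
#' @param smoothing_window,prominence_min Passed to [find_extrema()] for
#'   the extremum-offset component.
#' @return List with `max_abs_diff`, `rms_diff` and `extrema_offsets_nm`
#'   (named numeric vector, wavelength of `b` minus wavelength of `a` for
#'   matched extrema).
#' @export
compare_spectra <- function(a, b, smoothing_window = 5L,
                            prominence_min = 0.005) {
  stopifnot(inherits(a, "wing_spectrum"), inherits(b, "wing_spectrum"))
  lo <- max(min(a$wavelength_nm), min(b$wavelength_nm))
  hi <- min(max(a$wavelength_nm), max(b$wavelength_nm))
  if (lo >= hi) stop_invalid("spectra have disjoint wavelength bands")
  na <- sum(a$wavelength_nm >= lo & a$wavelength_nm <= hi)
  nb <- sum(b$wavelength_nm >= lo & b$wavelength_nm <= hi)
  coarse <- if (na <= nb) a else b
  grid <- coarse$wavelength_nm[coarse$wavelength_nm >= lo &
                                 coarse$wavelength_nm <= hi]
  va <- approx(a$wavelength_nm, a$value, xout = grid)$y
  vb <- approx(b$wavelength_nm, b$value, xout = grid)$y
  d <- vb - va
  offs <- numeric(0)
  ea <- try(find_extrema(a, c(lo, hi), smoothing_window, prominence_min),
            silent = TRUE)
  eb <- try(find_extrema(b, c(lo, hi), smoothing_window, prominence_min),
            silent = TRUE)
  if (!inherits(ea, "try-error") && !inherits(eb, "try-error")) {
    for (ty in c("max", "min")) {
      wa <- ea$wavelength_nm[ea$type == ty]
      wb <- eb$wavelength_nm[eb$type == ty]
      m <- min(length(wa), length(wb))
      if (m > 0L) {
        o <- wb[seq_len(m)] - wa[seq_len(m)]
        names(o) <- paste0(ty, seq_len(m))
        offs <- c(offs, o)
      }
    }
  }
  list(max_abs_diff = max(abs(d)),
       rms_diff = sqrt(mean(d^2)),
       extrema_offsets_nm = offs)
}

#' Read / write spectra as two-column CSV
#'
#' The CSV dialect is `wavelength_nm,value` with the spectrum kind recorded
#' in a `# kind:` comment line above the header.
#'
#' @param path File path.
#' @param s A [spectrum()] (for writing).
#' @return `read_spectrum_csv` returns a [spectrum()];
#'   `write_spectrum_csv` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("spectrum file not found: %s", path)
  first <- readLines(path, n = 1L)
  kind <- "reflectance"
  if (grepl("^#\\s*kind:", first)) {
    kind <- trimws(sub("^#\\s*kind:\\s*", "", first))
  }
  df <- read.csv(path, comment.char = "#")
  if (!all(c("wavelength_nm", "value") %in% names(df))) {
    stop_invalid("%s: expected columns wavelength_nm,value", path)
  }
  spectrum(df$wavelength_nm, df$value, kind = kind,
           provenance = list(file = path))
}

#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "wing_spectrum"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", attr(s, "kind")), con)
  write.csv(as.data.frame(s), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
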