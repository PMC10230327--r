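#' Construct a sessile-droplet contour
#'
#' Ordered silhouette coordinates of a sessile drop plus the substrate
#' baseline (`y` increases away from the substrate). At least 10 points
#' must lie above the baseline and the contour must have positive lateral
#' extent.
#'
#' @param points `data.frame` (or matrix) with columns `x` and `y`, in a
#'   consistent length unit (um or px).
#' @param baseline Substrate line `y` value (same unit).
#' @return An object of class `droplet_contour`.
#' @export
droplet_contour <- function(points, baseline = 0) {
  points <- as.data.frame(points)
  if (!all(c("x", "y") %in% names(points))) {
    stop_invalid("`points` needs columns x and y")
  }
  if (anyNA(points[, c("x", "y")]) ||
      any(!is.finite(as.matrix(points[, c("x", "y")])))) {
    stop_invalid("contour coordinates must be finite")
  }
  check_number(baseline, "baseline")
  above <- points$y > baseline
  if (sum(above) < 10L) {
    stop_invalid("contour must have >= 10 points above the baseline (has %d)",
                 sum(above))
  }
  if (diff(range(points$x[above])) <= 0) {
    stop_invalid("contour x-extent must be positive")
  }
  structure(list(points = points[, c("x", "y")], baseline = baseline),
            class = "droplet_contour")
}

# Algebraic (Kasa) circle fit followed by Gauss-Newton refinement of the
# geometric distance. Returns center and radius.
fit_circle <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  qr_A <- qr(A)
  if (qr_A$rank < 3L) {
    stop_invalid("degenerate contour: points are collinear, circle fit failed")
  }
  sol <- qr.coef(qr_A, b)
  xc <- sol[1L]
  yc <- sol[2L]
  r <- sqrt(sol[3L] + xc^2 + yc^2)
  for (iter in 1:25) {
    dx <- x - xc
    dy <- y - yc
    d <- sqrt(dx^2 + dy^2)
    if (any(d < 1e-12)) break
    resid <- d - r
    J <- cbind(-dx / d, -dy / d, rep(-1, length(d)))
    step <- tryCatch(qr.coef(qr(J), -resid), error = function(e) NULL)
    if (is.null(step) || anyNA(step)) break
    xc <- xc + step[1L]
    yc <- yc + step[2L]
    r <- r + step[3L]
    if (max(abs(step)) < 1e-12 * max(r, 1)) break
  }
  list(xc = unname(xc), yc = unname(yc), r = unname(r))
}

#' Static contact angle from a droplet contour
#'
#' Fits a circle (spherical-cap assumption, appropriate for ~1 ul drops)
#' to the contour points above the baseline by least squares, then reads
#' the contact angle where the circle crosses the baseline: for a circle
#' of radius `r` whose center sits at height `c` above the baseline, the
#' angle through the liquid is `theta = 90 + asin(c / r)` degrees (`c < 0`
#' gives angles below 90). Points within `exclude_frac` of the droplet
#' height above the baseline are excluded from the fit to mimic the
#' reflection-artifact exclusion zone of goniometer software. The fitted
#' circle is symmetric, so the left and right angles coincide; both are
#' reported for interface compatibility with goniometer output.
#'
#' @param contour A [droplet_contour()].
#' @param exclude_frac Fraction of the droplet height above the baseline
#'   below which points are dropped from the fit (default 0.02).
#' @return An object of class `contact_angle_result`: list with
#'   `theta_left_deg`, `theta_right_deg`, `theta_mean_deg`,
#'   `residual_rms` (RMS point-to-circle distance), `circle` and
#'   `n_points_used`.
#' @export
contact_angle <- function(contour, exclude_frac = 0.02) {
  stopifnot(inherits(contour, "droplet_contour"))
  p <- contour$points
  h <- p$y - contour$baseline
  hmax <- max(h)
  keep <- h > exclude_frac * hmax
  if (sum(keep) < 5L) {
    stop_invalid("too few contour points left after the exclusion zone")
  }
  fit <- fit_circle(p$x[keep], p$y[keep])
  cheight <- fit$yc - contour$baseline
  if (abs(cheight) >= fit$r) {
    stop_invalid("fitted circle does not intersect the baseline (no contact line)")
  }
  theta <- 90 + asin(cheight / fit$r) * 180 / pi
  d <- sqrt((p$x[keep] - fit$xc)^2 + (p$y[keep] - fit$yc)^2)
  structure(list(theta_left_deg = theta, theta_right_deg = theta,
                 theta_mean_deg = theta,
                 residual_rms = sqrt(mean((d - fit$r)^2)),
                 circle = fit, n_points_used = sum(keep)),
            class = "contact_angle_result")
}

#' @export
print.contact_angle_result <- function(x, ...) {
  cat(sprintf(
    "<contact_angle_result> theta = %.2f deg (left %.2f / right %.2f), fit RMS %.3g, %d points\n",
    x$theta_mean_deg, x$theta_left_deg, x$theta_right_deg, x$residual_rms,
    x$n_points_used))
  invisible(x)
}

#' Compare two groups of contact angles by t-test
#'
#' Paired (default) or pooled-variance unpaired two-sided t-test. Paired
#' comparisons use `n - 1` degrees of freedom; unpaired use
#' `n_a + n_b - 2`. A zero-variance configuration with zero mean
#' difference returns `t = 0, p = 1` by convention; zero variance with a
#' nonzero difference is degenerate data and raises an error.
#'
#' @param a,b Numeric vectors of angles in degrees (`n >= 2` each; equal
#'   lengths when `paired`).
#' @param paired Logical (default `TRUE`).
#' @return List with `t`, `df` and `p`.
#' @export
compare_groups <- function(a, b, paired = TRUE) {
  if (length(a) < 2L || length(b) < 2L) {
    stop_invalid("each group needs n >= 2")
  }
  if (paired && length(a) != length(b)) {
    stop_invalid("paired comparison requires equal group lengths")
  }
  if (paired) {
    d <- a - b
    if (sd(d) == 0) {
      if (mean(d) == 0) {
        return(list(t = 0, df = length(d) - 1L, p = 1))
      }
      stop_invalid("degenerate data: zero variance with nonzero mean difference")
    }
    tt <- t.test(a, b, paired = TRUE)
  } else {
    if (sd(a) == 0 && sd(b) == 0) {
      if (mean(a) == mean(b)) {
        return(list(t = 0, df = length(a) + length(b) - 2L, p = 1))
      }
      stop_invalid("degenerate data: zero variance with nonzero mean difference")
    }
    tt <- t.test(a, b, var.equal = TRUE)
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Classify wettability from a static contact angle
#'
#' Hydrophobic above 90 degrees (exclusive), superhydrophobic above 150
#' degrees (exclusive), hydrophilic otherwise.
#'
#' @param theta_deg Contact angle(s) in degrees, each in (0, 180).
#' @return Character vector of labels.
#' @export
classify_wettability <- function(theta_deg) {
  if (any(!is.finite(theta_deg)) || any(theta_deg <= 0) ||
      any(theta_deg >= 180)) {
    stop_invalid("contact angles must lie in (0, 180) degrees")
  }
  ifelse(theta_deg > 150, "superhydrophobic",
         ifelse(theta_deg > 90, "hydrophobic", "hydrophilic"))
}

#' Read a droplet contour from CSV
#'
#' Expects columns `x,y`; the baseline may be recorded as a
#' `# baseline: <y>` comment line, or supplied via `baseline` (the
#' argument wins).
#'
#' @param path CSV path.
#' @param baseline Optional baseline override.
#' @return A [droplet_contour()].
#' @export
read_contour_csv <- function(path, baseline = NULL) {
  if (!file.exists(path)) stop_invalid("contour file not found: %s", path)
  first <- readLines(path, n = 1L)
  file_baseline <- if (grepl("^#\\s*baseline:", first)) {
    as.numeric(trimws(sub("^#\\s*baseline:\\s*", "", first)))
  } else {
    NULL
  }
  df <- read.csv(path, comment.char = "#")
  bl <- if (!is.null(baseline)) baseline else file_baseline
  if (is.null(bl)) {
    stop_invalid("%s: no baseline in header and none supplied", path)
  }
  droplet_contour(df, baseline = bl)
}
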