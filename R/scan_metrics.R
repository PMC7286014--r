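#' Local-polynomial (Savitzky-Golay-style) smoothing of a scan curve
#'
#' Least-squares polynomial smoothing on a sliding window of sample points.
#' Unlike classical Savitzky-Golay convolution weights this fit uses the
#' actual sample positions, so unevenly spaced scans are handled correctly.
#' Near the curve ends the window shrinks to the available points (degree is
#' lowered if fewer than `polyorder + 1` points remain); polynomials of
#' degree up to `polyorder` are reproduced exactly everywhere.
#'
#' @param curve A [scan_curve()].
#' @param window Odd number of points in the fit window (3 to length of
#'   curve). Default 7.
#' @param polyorder Polynomial degree, less than `window`. Default 2.
#' @return A smoothed [scan_curve()] on the same positions.
#' @export
smooth_curve <- function(curve, window = 7L, polyorder = 2L) {
  stopifnot(inherits(curve, "scan_curve"))
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  n <- length(curve$positions)
  if (window %% 2L == 0L || window < 3L || window > n) {
    stop_sf("window must be odd and within [3, length(curve)]",
            "sfdose_argument_error")
  }
  if (polyorder < 0L || polyorder >= window) {
    stop_sf("polyorder must be non-negative and smaller than window",
            "sfdose_argument_error")
  }
  h <- (window - 1L) %/% 2L
  x <- curve$positions; y <- curve$values
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- max(1L, i - h):min(n, i + h)   # shrinking end windows
    deg <- min(polyorder, length(idx) - 1L)
    xi <- x[idx] - x[i]                   # centre for conditioning
    X <- outer(xi, 0:deg, `^`)
    beta <- qr.coef(qr(X), y[idx])
    out[i] <- beta[1L]                    # fitted value at x[i]
  }
  out[out < 0] <- 0   # smoothing must not create negative dose
  res <- curve
  res$values <- out
  res
}

#' Normalise a depth-dose curve to 100 at its maximum
#'
#' @param curve A depth-axis [scan_curve()] with positive maximum.
#' @return The curve rescaled so `max(values) == 100`, with
#'   `normalized = "max100"`.
#' @export
normalize_to_max <- function(curve) {
  stopifnot(inherits(curve, "scan_curve"))
  if (curve$axis != "depth") {
    stop_sf("normalize_to_max applies to depth curves", "sfdose_argument_error")
  }
  m <- max(curve$values)
  if (m <= 0) {
    stop_sf("cannot normalise an all-zero curve", "sfdose_degenerate_error")
  }
  curve$values <- curve$values * (100 / m)
  curve$normalized <- "max100"
  curve
}

#' Percentage depth dose at a given depth
#'
#' Linear interpolation of a max-normalised depth-dose curve.
#'
#' @param curve A depth-axis [scan_curve()] normalised with
#'   [normalize_to_max()].
#' @param depth_mm Query depth in mm, inside the scanned range.
#' @return PDD in percent of the maximum.
#' @export
pdd_at_depth <- function(curve, depth_mm) {
  stopifnot(inherits(curve, "scan_curve"))
  if (curve$axis != "depth") {
    stop_sf("pdd_at_depth applies to depth curves", "sfdose_argument_error")
  }
  if (curve$normalized != "max100") {
    stop_sf("curve must be normalised to max = 100 first (normalize_to_max)",
            "sfdose_argument_error")
  }
  rng <- range(curve$positions)
  if (any(depth_mm < rng[1] | depth_mm > rng[2])) {
    stop_sf(sprintf("depth %s mm outside scan range [%g, %g] mm",
                    paste(depth_mm, collapse = ", "), rng[1], rng[2]),
            "sfdose_range_error")
  }
  stats::approx(curve$positions, curve$values, xout = depth_mm)$y
}

#' Depth of maximum dose
#'
#' Locates the maximum sample of a depth-dose curve and refines it with a
#' parabola through the maximum and its two neighbours (exact for locally
#' quadratic peaks). A flat plateau of tied maxima returns the plateau
#' midpoint. A maximum at the scan boundary cannot be refined: the boundary
#' depth is returned with a warning.
#'
#' @param curve A depth-axis [scan_curve()].
#' @return Depth of maximum dose, mm.
#' @export
find_dmax <- function(curve) {
  stopifnot(inherits(curve, "scan_curve"))
  if (curve$axis != "depth") {
    stop_sf("find_dmax applies to depth curves", "sfdose_argument_error")
  }
  x <- curve$positions; y <- curve$values
  n <- length(y)
  imax <- which(y == max(y))
  if (length(imax) > 1L) {
    # tie: midpoint of the maximal plateau (symmetric, deterministic)
    return((x[min(imax)] + x[max(imax)]) / 2)
  }
  i <- imax
  if (i == 1L || i == n) {
    warn_sf("maximum lies at the scan boundary; depth not refined",
            "sfdose_boundary_warning")
    return(x[i])
  }
  # vertex of the parabola through (x[i-1], y[i-1]), (x[i], y[i]), (x[i+1], y[i+1])
  x1 <- x[i - 1L]; x2 <- x[i]; x3 <- x[i + 1L]
  y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
  d <- (x1 - x2) * (x1 - x3) * (x2 - x3)
  a <- (x3 * (y2 - y1) + x2 * (y1 - y3) + x1 * (y3 - y2)) / d
  b <- (x3^2 * (y1 - y2) + x2^2 * (y3 - y1) + x1^2 * (y2 - y3)) / d
  if (a >= 0) return(x2)          # degenerate curvature: keep the sample
  vx <- -b / (2 * a)
  min(max(vx, x1), x3)            # clamp to the bracketing interval
}

#' Normalise a lateral profile to 100 on the central axis
#'
#' @param profile A lateral [scan_curve()] whose position range includes 0.
#' @return The profile rescaled so its interpolated value at position 0 is
#'   100, with `normalized = "cax100"`.
#' @export
normalize_to_cax <- function(profile) {
  stopifnot(inherits(profile, "scan_curve"))
  if (profile$axis == "depth") {
    stop_sf("normalize_to_cax applies to lateral profiles",
            "sfdose_argument_error")
  }
  rng <- range(profile$positions)
  if (rng[1] > 0 || rng[2] < 0) {
    stop_sf("profile does not cover position 0", "sfdose_range_error")
  }
  v0 <- stats::approx(profile$positions, profile$values, xout = 0)$y
  if (v0 <= 0) {
    stop_sf("central-axis value is not positive", "sfdose_degenerate_error")
  }
  profile$values <- profile$values * (100 / v0)
  profile$normalized <- "cax100"
  profile
}

check_cax100 <- function(profile) {
  stopifnot(inherits(profile, "scan_curve"))
  if (profile$axis == "depth") {
    stop_sf("a lateral profile is required", "sfdose_argument_error")
  }
  if (profile$normalized != "cax100") {
    stop_sf("profile must be normalised to CAX = 100 first (normalize_to_cax)",
            "sfdose_argument_error")
  }
  invisible(profile)
}

#' Positions where a profile crosses a dose level
#'
#' Finds the single rising (left) and single falling (right) crossing of a
#' CAX-normalised profile through `level`, each located by linear
#' interpolation between the bracketing samples.
#'
#' @param profile A lateral [scan_curve()] normalised with
#'   [normalize_to_cax()].
#' @param level Dose level in percent of the CAX value (e.g. 50).
#' @return Named numeric `c(left_mm, right_mm)` with `left_mm < right_mm`.
#' @export
level_crossings <- function(profile, level) {
  check_cax100(profile)
  x <- profile$positions; y <- profile$values
  s <- y - level
  idx <- which(s[-length(s)] * s[-1] < 0 | (s[-length(s)] == 0 & s[-1] != 0))
  # classify each bracketing interval by slope sign
  rising <- idx[y[idx + 1L] > y[idx]]
  falling <- idx[y[idx + 1L] < y[idx]]
  if (length(rising) != 1L) {
    stop_sf(sprintf(
      "left side: expected exactly one rising crossing of %g%%, found %d",
      level, length(rising)), "sfdose_shape_error")
  }
  if (length(falling) != 1L) {
    stop_sf(sprintf(
      "right side: expected exactly one falling crossing of %g%%, found %d",
      level, length(falling)), "sfdose_shape_error")
  }
  interp_at <- function(i) {
    x[i] + (level - y[i]) * (x[i + 1L] - x[i]) / (y[i + 1L] - y[i])
  }
  out <- c(left_mm = interp_at(rising), right_mm = interp_at(falling))
  if (out[1] >= out[2]) {
    stop_sf("crossings are not ordered left < right", "sfdose_shape_error")
  }
  out
}

#' Full width at half maximum of a lateral profile
#'
#' Distance between the 50% crossings of a CAX-normalised profile; the
#' dosimetric field width.
#'
#' @inheritParams level_crossings
#' @return FWHM in mm.
#' @export
fwhm <- function(profile) {
  cr <- level_crossings(profile, 50)
  unname(cr["right_mm"] - cr["left_mm"])
}

#' 20-80% penumbra widths of a lateral profile
#'
#' Per edge, the lateral distance between the 20% and 80% dose levels.
#'
#' @inheritParams level_crossings
#' @return Named numeric `c(left_mm, right_mm)`, both positive.
#' @export
penumbra_widths <- function(profile) {
  c20 <- level_crossings(profile, 20)
  c80 <- level_crossings(profile, 80)
  c(left_mm = unname(abs(c80["left_mm"] - c20["left_mm"])),
    right_mm = unname(abs(c80["right_mm"] - c20["right_mm"])))
}

#' Recenter a lateral profile on its 50% midpoint
#'
#' Shifts positions so the midpoint of the 50% crossings sits at 0. The
#' profile is CAX-normalised internally (on the shifted curve) if needed.
#'
#' @param profile A lateral [scan_curve()].
#' @return The recentred profile (normalisation state preserved).
#' @export
recenter <- function(profile) {
  stopifnot(inherits(profile, "scan_curve"))
  p <- if (profile$normalized == "cax100") profile else normalize_to_cax(profile)
  cr <- level_crossings(p, 50)
  mid <- (cr["left_mm"] + cr["right_mm"]) / 2
  profile$positions <- profile$positions - unname(mid)
  profile
}

#' Shift a scan curve along its axis
#'
#' Applies a constant coordinate offset, e.g. an effective-point-of-
#' measurement correction to a chamber-scanned depth dose. No shift is ever
#' applied implicitly: detectors scanned with their effective point at the
#' surface of the active volume need none, and whether a chamber scan was
#' already shifted by the acquisition software is not knowable from the
#' file, so the offset is an explicit user decision.
#'
#' @param curve A [scan_curve()].
#' @param offset_mm Offset added to every position (mm).
#' @return The shifted curve.
#' @export
shift_curve <- function(curve, offset_mm) {
  stopifnot(inherits(curve, "scan_curve"))
  if (!is.numeric(offset_mm) || length(offset_mm) != 1L ||
      !is.finite(offset_mm)) {
    stop_sf("offset_mm must be a finite number", "sfdose_argument_error")
  }
  curve$positions <- curve$positions + offset_mm
  curve
}

#' Summary metrics of a scan curve
#'
#' Convenience wrapper: for a depth curve, d_max and PDD at the requested
#' depth; for a lateral profile, FWHM and 20-80% penumbra widths after
#' CAX normalisation and recentering.
#'
#' @param curve A [scan_curve()].
#' @param pdd_depth_mm Depth (mm) at which to report PDD for depth curves.
#' @return A named list of metrics.
#' @export
scan_metrics <- function(curve, pdd_depth_mm = 100) {
  stopifnot(inherits(curve, "scan_curve"))
  if (curve$axis == "depth") {
    cmax <- normalize_to_max(curve)
    list(axis = "depth",
         detector = curve$detector_id,
         dmax_mm = find_dmax(cmax),
         pdd_depth_mm = pdd_depth_mm,
         pdd_percent = pdd_at_depth(cmax, pdd_depth_mm))
  } else {
    p <- recenter(curve)
    p <- normalize_to_cax(p)
    pen <- penumbra_widths(p)
    list(axis = curve$axis,
         detector = curve$detector_id,
         fwhm_mm = fwhm(p),
         penumbra_left_mm = unname(pen["left_mm"]),
         penumbra_right_mm = unname(pen["right_mm"]))
  }
}
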