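# Fixture builders used across the suite. The erf-edge builder is written
# from the normal-CDF form directly so it stays an independent construction
# from the package's own profile generator.

# Flat-top profile with linear edges; 50% sits exactly at +-width/2 and the
# 80-20 drop spans 0.6 * edge_mm per side.
trapezoid_profile <- function(width_mm = 20, edge_mm = 5, grid_mm = 0.5,
                              top = 100, shift_mm = 0, ...) {
  x <- seq(-width_mm, width_mm, by = grid_mm)
  v <- top * pmin(1, pmax(0, ((width_mm + edge_mm) / 2 - abs(x)) / edge_mm))
  scan_curve(axis = "crossline", positions = x + shift_mm, values = v,
             scan_depth_mm = 100, ...)
}

# Sum-of-normal-CDF edge profile: Phi((w/2 - x)/sigma) + Phi((w/2 + x)/sigma) - 1
erf_profile <- function(field_mm = 20, sigma_mm = 3, grid_mm = 0.2,
                        span = 2, amplitude = 1, ...) {
  half <- seq(0, span * field_mm, by = grid_mm)
  x <- c(-rev(half[-1]), half)
  v <- amplitude * (pnorm((field_mm / 2 - x) / sigma_mm) +
                    pnorm((field_mm / 2 + x) / sigma_mm) - 1)
  scan_curve(axis = "crossline", positions = x, values = v,
             scan_depth_mm = 100, ...)
}

# Brute-force level crossing: evaluate the profile's linear interpolant on a
# dense grid and take the first/last point at or above the level.
grid_crossing_oracle <- function(profile, level, step = 0.001) {
  xs <- seq(min(profile$positions), max(profile$positions), by = step)
  vs <- approx(profile$positions, profile$values, xout = xs)$y
  above <- which(vs >= level)
  c(left = xs[above[1]], right = xs[above[length(above)]])
}

expect_scalar_equal <- function(object, expected, tol = 1e-9) {
  expect_equal(unname(object), unname(expected), tolerance = tol)
}
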