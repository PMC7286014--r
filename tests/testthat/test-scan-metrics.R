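test_that("depth-dose normalisation scales the maximum to 100", {
  cv <- scan_curve("depth", c(0, 5, 15, 30, 60), c(1, 2, 4, 2, 1))
  n1 <- normalize_to_max(cv)
  expect_equal(n1$values, c(25, 50, 100, 50, 25))
  expect_identical(n1$normalized, "max100")
  expect_equal(normalize_to_max(n1)$values, n1$values)  # idempotent
  zero <- scan_curve("depth", 0:4, rep(0, 5))
  expect_error(normalize_to_max(zero), class = "sfdose_degenerate_error")
})

test_that("pdd_at_depth interpolates linearly and respects the scan range", {
  cv <- scan_curve("depth", c(0, 15, 95, 100, 105), c(50, 100, 68, 66.5, 66),
                   normalized = "max100")
  expect_scalar_equal(pdd_at_depth(cv, 100), 66.5)   # on-grid lookup
  cv2 <- scan_curve("depth", c(0, 15, 50, 95, 105), c(50, 100, 90, 68, 66),
                    normalized = "max100")
  expect_scalar_equal(pdd_at_depth(cv2, 100), 67.0)  # midpoint of 68 and 66
  expect_error(pdd_at_depth(cv2, 200), class = "sfdose_range_error")
  raw <- scan_curve("depth", c(0, 15, 50, 95, 105), c(50, 100, 90, 68, 66))
  expect_error(pdd_at_depth(raw, 50), class = "sfdose_argument_error")
})

test_that("synthetic depth dose matches its closed form at 10 cm", {
  beam <- beam_model()
  pdd <- true_pdd(beam, 10, seq(0, 310, by = 0.5))
  a <- beam$buildup_per_mm; mu <- beam$mu_per_mm
  shape <- function(d) (1 - exp(-a * d)) * exp(-mu * d)
  closed <- 100 * shape(100) / shape(log(1 + a / mu) / a)
  expect_equal(pdd_at_depth(pdd, 100), closed, tolerance = 5e-4)
})

test_that("find_dmax refines the peak parabolically and handles plateaus", {
  x <- seq(0, 30, by = 1)
  peak_at <- function(p) scan_curve("depth", x, 100 - 0.4 * (x - p)^2)
  expect_scalar_equal(find_dmax(peak_at(15)), 15)
  expect_equal(find_dmax(peak_at(14.3)), 14.3, tolerance = 0.01)

  plateau <- scan_curve("depth", 0:9, c(1, 2, 5, 9, 9, 9, 9, 5, 2, 1))
  expect_scalar_equal(find_dmax(plateau), 4.5)  # midpoint of tied maxima

  falling <- scan_curve("depth", 0:5, c(10, 9, 8, 7, 6, 5))
  expect_warning(d <- find_dmax(falling), class = "sfdose_boundary_warning")
  expect_identical(d, 0)
})

test_that("generator d_max is recovered from a 0.5 mm sampled depth dose", {
  beam <- beam_model(dmax_mm = 15)
  pdd <- true_pdd(beam, 10, seq(0, 310, by = 0.5))
  expect_equal(find_dmax(pdd), 15, tolerance = 0.25)
})

test_that("profile CAX normalisation fixes the value at 0 to 100", {
  p <- trapezoid_profile(top = 7)
  n <- normalize_to_cax(p)
  expect_scalar_equal(approx(n$positions, n$values, xout = 0)$y, 100)
  expect_identical(n$normalized, "cax100")
  off <- scan_curve("crossline", seq(5, 25, 5), rep(1, 5), scan_depth_mm = 100)
  expect_error(normalize_to_cax(off), class = "sfdose_range_error")
})

test_that("level crossings are located by linear interpolation", {
  p <- normalize_to_cax(trapezoid_profile(width_mm = 20))
  expect_equal(level_crossings(p, 50), c(left_mm = -10, right_mm = 10))

  # bracketing samples (4 mm, 60%) and (5 mm, 40%) put the 50% cut at 4.5 mm
  q <- normalize_to_cax(scan_curve(
    "crossline", c(-5, -4, 0, 4, 5), c(40, 60, 100, 60, 40),
    scan_depth_mm = 100))
  expect_equal(unname(level_crossings(q, 50)), c(-4.5, 4.5))

  mono <- normalize_to_cax(scan_curve(
    "crossline", c(-1, 0, 1, 2, 3), c(90, 100, 110, 120, 130),
    scan_depth_mm = 100))
  expect_error(level_crossings(mono, 50), "left side",
               class = "sfdose_shape_error")
})

test_that("crossings on erf-edge profiles agree with a dense-grid search", {
  for (field in c(10, 20, 30)) {
    p <- normalize_to_cax(erf_profile(field_mm = field, sigma_mm = 3))
    for (level in c(20, 50, 80)) {
      got <- level_crossings(p, level)
      oracle <- grid_crossing_oracle(p, level)
      expect_equal(unname(got["left_mm"]), unname(oracle["left"]),
                   tolerance = 0.01)
      expect_equal(unname(got["right_mm"]), unname(oracle["right"]),
                   tolerance = 0.01)
    }
  }
})

test_that("fwhm and penumbra match their closed forms on erf edges", {
  p <- normalize_to_cax(erf_profile(field_mm = 20, sigma_mm = 3))
  expect_equal(fwhm(p), 20, tolerance = 0.05)

  p3 <- normalize_to_cax(erf_profile(field_mm = 30, sigma_mm = 3))
  pen <- penumbra_widths(p3)
  closed <- 3 * (qnorm(0.8) - qnorm(0.2))   # 1.683 * sigma
  expect_equal(unname(pen["left_mm"]), closed, tolerance = 0.01 * closed)
  expect_equal(unname(pen["right_mm"]), closed, tolerance = 0.01 * closed)

  tz <- normalize_to_cax(trapezoid_profile(width_mm = 20, edge_mm = 5))
  expect_equal(unname(penumbra_widths(tz)), c(3, 3))
})

test_that("fwhm and penumbra are invariant to value scaling and recentering", {
  base <- erf_profile(field_mm = 20, sigma_mm = 3)
  scaled <- base; scaled$values <- base$values * 37.2
  shifted <- base; shifted$positions <- base$positions + 2
  f0 <- fwhm(normalize_to_cax(base))
  expect_equal(fwhm(normalize_to_cax(scaled)), f0, tolerance = 1e-12)
  expect_equal(fwhm(normalize_to_cax(recenter(shifted))), f0,
               tolerance = 1e-9)
  p0 <- penumbra_widths(normalize_to_cax(base))
  expect_equal(penumbra_widths(normalize_to_cax(scaled)), p0,
               tolerance = 1e-12)
})

test_that("recenter zeroes the 50% midpoint and is idempotent", {
  p <- trapezoid_profile(shift_mm = 2)
  r <- recenter(p)
  cr <- level_crossings(normalize_to_cax(r), 50)
  expect_equal(unname(cr["left_mm"] + cr["right_mm"]), 0, tolerance = 1e-9)
  r2 <- recenter(r)
  expect_equal(r2$positions, r$positions, tolerance = 1e-9)
  sym <- trapezoid_profile()
  expect_equal(recenter(sym)$positions, sym$positions, tolerance = 1e-12)
})

test_that("shift_curve offsets positions explicitly and only on request", {
  cv <- scan_curve("depth", c(0, 5, 15, 30, 60), c(1, 2, 4, 2, 1))
  sh <- shift_curve(cv, -2)
  expect_equal(sh$positions, cv$positions - 2)
  expect_equal(sh$values, cv$values)
  expect_equal(shift_curve(sh, 2)$positions, cv$positions)
  expect_error(shift_curve(cv, NA), class = "sfdose_argument_error")
})

test_that("aperture convolution broadens the penumbra monotonically", {
  base <- erf_profile(field_mm = 20, sigma_mm = 3)
  widths <- c(0, 1, 2, 3.6, 5)
  pens <- vapply(widths, function(a) {
    p <- normalize_to_cax(convolve_aperture(base, a))
    mean(penumbra_widths(p))
  }, 0)
  expect_true(all(diff(pens) >= -1e-9))
  expect_gt(pens[4], pens[1])  # chamber-sized aperture vs point detector
})
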