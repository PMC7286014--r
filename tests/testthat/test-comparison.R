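test_that("sample_sd uses the n-1 divisor", {
  expect_equal(sample_sd(c(0.674, 0.736, 0.668)), 0.03765, tolerance = 1e-3)
  expect_equal(round(sample_sd(c(0.674, 0.736, 0.668)), 2), 0.04)
  expect_identical(sample_sd(c(3, 3, 3)), 0)
  set.seed(5)
  for (i in 1:50) {
    x <- runif(3, 0.5, 1.5)
    manual <- sqrt(sum((x - mean(x))^2) / (length(x) - 1))
    expect_equal(sample_sd(x), manual, tolerance = 1e-12)
  }
  expect_error(sample_sd(1), class = "sfdose_argument_error")
})

test_that("percent_sd is SD/mean x 100 and scale invariant", {
  expect_equal(round(percent_sd(c(0.674, 0.736, 0.668)), 1), 5.4)
  expect_identical(percent_sd(c(0.865, 0.865, 0.865)), 0)
  set.seed(6)
  x <- runif(5, 1, 2)
  expect_equal(percent_sd(10 * x), percent_sd(x), tolerance = 1e-12)
  expect_error(percent_sd(c(-2, 1, -2)), class = "sfdose_argument_error")
})

test_that("summarize_fof pools only the requested detectors", {
  wide <- utils::read.csv(sf_example("fof_uncorrected_6mv.csv"))
  rep <- summarize_fof(wide[, c("side_cm", "CC01", "PFD", "EFD",
                                "EDGE", "CC13")],
                       detectors_in_stats = c("CC01", "PFD", "EFD"))
  expect_equal(round(rep$percent_sd, 1), c(1.1, 1.7, 2.0, 2.6, 5.4))
  expect_true(all(c("EDGE", "CC13") %in% names(rep)))  # raw, not pooled
  expect_error(summarize_fof(wide[, c("side_cm", "CC01")],
                             detectors_in_stats = "CC01"),
               class = "sfdose_argument_error")
  expect_error(summarize_fof(wide, detectors_in_stats = c("CC01", "NOPE")),
               class = "sfdose_consistency_error")
})

test_that("fof_wide aligns tables on a shared field index", {
  geoms <- data.frame(side_cm = c(4, 10), sclin_cm = c(4.4, 11))
  kt <- k_factor_table("X", c(4.4, 11), c(1.01, 1))
  mk <- function(det, v) {
    build_fof_table(list(reading_set(det, 4, rep(v, 3)),
                         reading_set(det, 10, rep(1, 3))), geoms,
                    k_factor_table(det, c(4.4, 11), c(1.01, 1)))
  }
  tabs <- list(A = mk("A", 0.86), B = mk("B", 0.87))
  w <- fof_wide(tabs, "fof_uncorrected")
  expect_identical(names(w), c("collimator_side_cm", "A", "B"))
  expect_equal(w$A[w$collimator_side_cm == 4], 0.86, tolerance = 1e-12)

  short <- mk("C", 0.85)[1, , drop = FALSE]
  expect_error(fof_wide(list(A = tabs$A, C = short)),
               class = "sfdose_consistency_error")
})

test_that("mlc_jaw_ratios reproduces printed-style ratio columns", {
  mlc <- data.frame(collimator_side_cm = c(10, 4), fof = c(1, 0.870))
  jaw <- data.frame(collimator_side_cm = c(10, 4), fof = c(1, 0.865))
  r <- mlc_jaw_ratios(mlc, jaw, value = "fof")
  expect_equal(r$ratio_printed, c(1.000, 1.006))
  same <- mlc_jaw_ratios(mlc, mlc, value = "fof")
  expect_true(all(same$ratio == 1))
  bad <- data.frame(collimator_side_cm = c(10, 3), fof = c(1, 0.86))
  expect_error(mlc_jaw_ratios(mlc, bad, value = "fof"),
               class = "sfdose_consistency_error")
})

test_that("mu_percent_sd summarises per case across datasets", {
  mu <- data.frame(
    case = rep(c("c1", "c2"), each = 3),
    technique = rep(c("symmetric", "imrt"), each = 3),
    dataset_label = rep(c("cc01", "pfd", "efd"), 2),
    mu = c(172, 183, 194, 3981, 3981, 3981))
  rep <- mu_percent_sd(mu)
  expect_equal(rep$mean_mu, c(183, 3981))
  expect_equal(rep$percent_sd[2], 0)
  expect_equal(rep$percent_sd[1], percent_sd(c(172, 183, 194)),
               tolerance = 1e-12)
  expect_error(mu_percent_sd(mu[c(1, 4:6), ]),
               class = "sfdose_argument_error")

  p <- tempfile(fileext = ".csv")
  utils::write.csv(mu, p, row.names = FALSE)
  expect_equal(read_mu_table(p)$mu, mu$mu)
  mu_bad <- mu; mu_bad$technique <- "freestyle"
  utils::write.csv(mu_bad, p, row.names = FALSE)
  expect_error(read_mu_table(p), class = "sfdose_parse_error")
})

test_that("percent_sd_from_summary recovers %SD from printed labels", {
  expect_equal(round(percent_sd_from_summary(183, 11.0), 1), 6.0)
  expect_equal(round(percent_sd_from_summary(3981, 100), 1), 2.5)
  expect_error(percent_sd_from_summary(0, 1), class = "sfdose_argument_error")
})

test_that("render_report writes rounded, re-readable reports", {
  wide <- utils::read.csv(sf_example("fof_uncorrected_6mv.csv"))
  rep <- summarize_fof(wide[, c("side_cm", "CC01", "PFD", "EFD")],
                       c("CC01", "PFD", "EFD"))
  p_csv <- tempfile(fileext = ".csv")
  render_report(rep, p_csv, "csv")
  back <- utils::read.csv(p_csv)
  expect_equal(back$percent_sd, round(rep$percent_sd, 1))
  expect_equal(back$mean, round(rep$mean, 3))

  p_json <- tempfile(fileext = ".json")
  render_report(rep, p_json, "json")
  back_j <- jsonlite::fromJSON(p_json)
  expect_equal(back_j$percent_sd, round(rep$percent_sd, 1))

  p_md <- tempfile(fileext = ".md")
  render_report(rep, p_md, "markdown")
  lines <- readLines(p_md)
  expect_length(lines, nrow(rep) + 2L)  # header + rule + one row per index

  expect_error(render_report(rep[0, ], tempfile(), "csv"),
               class = "sfdose_argument_error")
})
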