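msr_set <- function(det = "CC01", reading = 1, side = 10) {
  reading_set(det, side, rep(reading, 3))
}

test_that("uncorrected_fof is the ratio of mean readings", {
  clin <- reading_set("CC01", 1, c(0.673, 0.674, 0.675))
  expect_scalar_equal(uncorrected_fof(clin, msr_set()), 0.674)
  expect_scalar_equal(uncorrected_fof(msr_set(), msr_set()), 1)
  expect_error(uncorrected_fof(reading_set("PFD", 1, 1), msr_set()),
               class = "sfdose_consistency_error")
})

test_that("reading sets flag a coefficient of variation above 1%", {
  expect_warning(reading_set("CC01", 10, c(1.00, 1.04, 0.96)),
                 class = "sfdose_cv_warning")
  expect_silent(reading_set("CC01", 10, c(1.000, 1.001, 0.999)))
  expect_error(reading_set("CC01", 10, c(1, -1, 1)),
               class = "sfdose_argument_error")
  expect_error(reading_set("CC01", 10, numeric()),
               class = "sfdose_validation_error")
})

test_that("derive_k and corrected_fof are algebraic inverses", {
  expect_scalar_equal(derive_k(0.95, 0.95), 1)
  expect_equal(derive_k(1, 1.05), 1 / 1.05, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:20) {
    omega <- runif(1, 0.6, 1); u <- runif(1, 0.6, 1.1)
    expect_equal(corrected_fof(u, derive_k(omega, u)), omega,
                 tolerance = 1e-12)
  }
  expect_scalar_equal(corrected_fof(0.83, 1), 0.83)
  expect_equal(round(corrected_fof(0.794, 0.999), 3), 0.793)
  expect_error(corrected_fof(-1, 1), class = "sfdose_argument_error")
})

test_that("interpolate_k is linear, exact at knots, strict out of range", {
  kt <- k_factor_table("CC01", c(1.0, 2.0, 4.0), c(1.10, 1.02, 1.00))
  expect_scalar_equal(interpolate_k(kt, 2.0), 1.02)
  expect_scalar_equal(interpolate_k(kt, 1.5), 1.06)
  expect_error(interpolate_k(kt, 0.5), class = "sfdose_range_error")
  expect_warning(k0 <- interpolate_k(kt, 0.5, clamp = TRUE),
                 class = "sfdose_clamp_warning")
  expect_scalar_equal(k0, 1.10)

  # brute-force two-point formula on random monotone tables
  set.seed(23)
  for (rep in 1:10) {
    s <- sort(runif(8, 0.5, 10))
    k <- sort(runif(8, 0.9, 1.2), decreasing = TRUE)
    kt <- k_factor_table("X", s, k)
    q <- runif(10, min(s), max(s))
    manual <- vapply(q, function(x) {
      i <- findInterval(x, s, rightmost.closed = TRUE)
      k[i] + (k[i + 1] - k[i]) * (x - s[i]) / (s[i + 1] - s[i])
    }, 0)
    expect_equal(interpolate_k(kt, q), manual, tolerance = 1e-12)
  }
  expect_error(k_factor_table("X", c(2, 1), c(1, 1)),
               class = "sfdose_validation_error")
})

test_that("ifm_fof chains two corrected legs and degenerates to direct", {
  expect_scalar_equal(ifm_fof(0.8, 1, 1, 0.9, 1, 1), 0.72)
  # intermediate field == msr field with unit chamber correction
  m_clin <- 0.9438; m_msr <- 1.21; k <- 1.013
  expect_identical(ifm_fof(m_clin, m_msr, k, m_msr, m_msr, 1),
                   corrected_fof(m_clin / m_msr, k))
  expect_error(ifm_fof(1, 0, 1, 1, 1, 1), class = "sfdose_argument_error")
})

test_that("small_field_flag uses a strict threshold", {
  expect_true(small_field_flag(1.0, 2.0))
  expect_false(small_field_flag(6.54, 2.0))
  expect_false(small_field_flag(2.0, 2.0))  # boundary not flagged
})

test_that("build_fof_table assembles rows with the msr pinned at 1", {
  geoms <- data.frame(side_cm = c(1, 4, 10), sclin_cm = c(1.1, 4.4, 11))
  kt <- k_factor_table("CC01", c(1.1, 4.4, 11), c(1.05, 1.005, 1.0))
  readings <- list(
    reading_set("CC01", 1, rep(0.674, 3)),
    reading_set("CC01", 4, rep(0.859, 3)),
    msr_set("CC01"))
  tab <- build_fof_table(readings, geoms, kt)
  expect_s3_class(tab, "fof_table")
  expect_equal(nrow(tab), 3L)
  expect_identical(tab$fof_uncorrected[tab$collimator_side_cm == 10], 1)
  expect_identical(tab$fof_corrected[tab$collimator_side_cm == 10], 1)
  expect_equal(tab$fof_uncorrected[tab$collimator_side_cm == 1], 0.674,
               tolerance = 1e-12)
  expect_equal(tab$fof_corrected[tab$collimator_side_cm == 1], 0.674 * 1.05,
               tolerance = 1e-12)
  expect_true(tab$small_field[tab$collimator_side_cm == 1])
  expect_false(any(tab$small_field[tab$collimator_side_cm >= 4]))

  only_msr <- build_fof_table(list(msr_set("CC01")), geoms, kt)
  expect_equal(nrow(only_msr), 1L)
  expect_identical(only_msr$fof_corrected, 1)

  expect_error(build_fof_table(readings[1:2], geoms, kt),
               class = "sfdose_configuration_error")
})

test_that("non-monotone corrected factors warn rather than fail", {
  geoms <- data.frame(side_cm = c(2, 4, 10), sclin_cm = c(2.2, 4.4, 11))
  kt <- k_factor_table("CC01", c(2.2, 4.4, 11), c(1, 1, 1))
  readings <- list(
    reading_set("CC01", 2, rep(0.90, 3)),   # higher than the 4 cm field
    reading_set("CC01", 4, rep(0.86, 3)),
    msr_set("CC01"))
  expect_warning(tab <- build_fof_table(readings, geoms, kt),
                 class = "sfdose_monotonicity_warning")
  expect_equal(nrow(tab), 3L)
})

test_that("readings and k-table CSV readers reconstruct the inputs", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("detector,field_side_cm,defined_by,repeat,reading",
               "CC01,10,jaw,1,1.000", "CC01,10,jaw,2,1.001",
               "CC01,1,jaw,1,0.674", "CC01,1,jaw,2,0.675",
               "PFD,10,jaw,1,1.000", "PFD,1,jaw,1,0.736"), p)
  r <- read_readings(p)
  expect_named(r, c("CC01", "PFD"))
  expect_length(r$CC01, 2L)
  sides <- vapply(r$CC01, function(x) x$field$collimator_x_cm, 0)
  expect_equal(sort(sides), c(1, 10))

  kp <- tempfile(fileext = ".csv")
  writeLines(c("detector_model,sclin_cm,k", "EDGE,2.10,0.999",
               "EDGE,3.22,0.994"), kp)
  kt <- read_k_table(kp)
  expect_named(kt, "EDGE")
  expect_scalar_equal(interpolate_k(kt$EDGE, 2.10), 0.999)
  expect_scalar_equal(interpolate_k(kt$EDGE, 3.22), 0.994)
})

test_that("the bundled correction-factor example loads through read_k_table", {
  kt <- read_k_table(sf_example("edge_k_6mv.csv"))
  expect_scalar_equal(interpolate_k(kt$EDGE, 2.10), 0.999)
})
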