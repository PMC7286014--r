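erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Synthetic golden-beam model
#'
#' Parametric stand-in for a flattened 6 MV linac beam, rich enough to
#' exercise every stage of the analysis pipeline with known truth:
#' a bi-exponential depth dose, error-function-edged lateral profiles with
#' Gaussian source blurring, a saturating field-output curve, and a smooth
#' output drop from partial source occlusion below a characteristic field
#' size.
#'
#' The depth dose is `PDD(d) ~ (1 - exp(-a d)) * exp(-mu d)`; the build-up
#' coefficient `a` is solved from the closed-form depth of maximum,
#' `d_max = log(1 + a/mu) / a`. The true output factor is
#' `Omega(S) = (1 - c1 exp(-S/lambda)) * O(S)`, normalised so
#' `Omega(msr) = 1` exactly, with occlusion factor `O(S) = 1` for
#' `S >= w0` and a smooth quadratic drop below.
#'
#' @param energy Beam label (default `"6MV"`).
#' @param tpr2010 Beam quality index TPR20,10 (default 0.665).
#' @param dmax_mm Depth of maximum dose, mm (default 15).
#' @param mu_per_mm Attenuation coefficient beyond the build-up region,
#'   per mm (default 0.0048; places PDD(10 cm) near 68%).
#' @param sigma_mm Gaussian source-blur of the profile edges, mm (default 3).
#' @param w0_cm Field side below which source occlusion bites (default 1.2).
#' @param c_occ Occlusion drop strength (default 0.5).
#' @param c1,lambda_cm Output-factor plateau parameters (defaults 0.42 and
#'   5: output at 1 cm about 0.69 of the 10 cm reference, as for a flattened
#'   6 MV beam).
#' @param msr_cm Machine-specific reference field side, cm (default 10).
#' @return An object of class `beam_model`.
#' @export
beam_model <- function(energy = "6MV", tpr2010 = 0.665, dmax_mm = 15,
                       mu_per_mm = 0.0048, sigma_mm = 3, w0_cm = 1.2,
                       c_occ = 0.5, c1 = 0.42, lambda_cm = 5, msr_cm = 10) {
  for (nm in c("tpr2010", "dmax_mm", "mu_per_mm", "sigma_mm", "w0_cm",
               "lambda_cm", "msr_cm")) check_positive(get(nm), nm)
  if (c_occ < 0 || c_occ >= 1) {
    stop_sf("c_occ must be in [0, 1)", "sfdose_argument_error")
  }
  if (c1 <= 0 || c1 >= 1) {
    stop_sf("c1 must be in (0, 1)", "sfdose_argument_error")
  }
  # build-up coefficient from d_max = log(1 + a/mu)/a
  f <- function(a) log(1 + a / mu_per_mm) - a * dmax_mm
  a <- stats::uniroot(f, c(1e-4, 50), tol = 1e-14)$root
  structure(list(energy = energy, tpr2010 = tpr2010, dmax_mm = dmax_mm,
                 mu_per_mm = mu_per_mm, buildup_per_mm = a,
                 sigma_mm = sigma_mm, w0_cm = w0_cm, c_occ = c_occ,
                 c1 = c1, lambda_cm = lambda_cm, msr_cm = msr_cm),
            class = "beam_model")
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf(
    "<beam_model> %s (TPR20,10 %.3f): d_max %g mm, mu %.4f/mm, sigma %g mm\n",
    x$energy, x$tpr2010, x$dmax_mm, x$mu_per_mm, x$sigma_mm))
  invisible(x)
}

#' Source-occlusion output factor
#'
#' 1 for fields at least `w0_cm` wide, smooth quadratic drop below (the
#' primary-source occlusion that pulls small-field output down faster than
#' scatter loss alone).
#'
#' @param beam A [beam_model()].
#' @param sclin_cm Field side(s), cm.
#' @return Occlusion factor in (0, 1].
#' @export
occlusion_factor <- function(beam, sclin_cm) {
  stopifnot(inherits(beam, "beam_model"))
  check_positive(sclin_cm, "sclin_cm")
  ifelse(sclin_cm >= beam$w0_cm, 1,
         1 - beam$c_occ * (1 - sclin_cm / beam$w0_cm)^2)
}

#' True field output factor of the synthetic beam
#'
#' @param beam A [beam_model()].
#' @param sclin_cm Field side(s), cm.
#' @return `Omega(S)`, exactly 1 at the msr field.
#' @export
true_fof <- function(beam, sclin_cm) {
  stopifnot(inherits(beam, "beam_model"))
  check_positive(sclin_cm, "sclin_cm")
  num <- (1 - beam$c1 * exp(-sclin_cm / beam$lambda_cm)) *
    occlusion_factor(beam, sclin_cm)
  den <- (1 - beam$c1 * exp(-beam$msr_cm / beam$lambda_cm)) *
    occlusion_factor(beam, beam$msr_cm)
  num / den
}

#' Closed-form lateral dose of the synthetic beam
#'
#' Returns a function of the lateral coordinate (mm) evaluating the
#' blurred-aperture profile
#' `P(x) = O(S) * 0.5 * (erf((w/2 - x)/(sigma sqrt 2)) + erf((w/2 + x)/(sigma sqrt 2)))`
#' where `w` is the collimator side projected to the scan depth.
#'
#' @param beam A [beam_model()].
#' @param field_cm Collimator side (cm) at 100 cm.
#' @param depth_mm Scan depth (mm).
#' @param ssd_cm Source-surface distance (cm, default 100).
#' @return `function(x_mm)`.
#' @export
profile_fun <- function(beam, field_cm, depth_mm, ssd_cm = 100) {
  stopifnot(inherits(beam, "beam_model"))
  check_positive(field_cm, "field_cm")
  w <- field_cm * 10 * (ssd_cm * 10 + depth_mm) / 1000  # mm at scan depth
  s2 <- beam$sigma_mm * sqrt(2)
  O <- occlusion_factor(beam, field_cm)
  function(x) O * 0.5 * (erf((w / 2 - x) / s2) + erf((w / 2 + x) / s2))
}

#' Synthetic lateral profile
#'
#' Samples the closed-form blurred profile on a symmetric grid spanning
#' 1.5 projected field widths each side of the axis.
#'
#' @inheritParams profile_fun
#' @param axis `"crossline"` or `"inline"`.
#' @param grid_mm Sample spacing (default 0.2 mm).
#' @param detector_id Label for the emitted curve (default `"point"`, an
#'   idealised zero-volume detector).
#' @return A raw [scan_curve()].
#' @export
true_profile <- function(beam, field_cm, depth_mm, ssd_cm = 100,
                         axis = "crossline", grid_mm = 0.2,
                         detector_id = "point") {
  w <- field_cm * 10 * (ssd_cm * 10 + depth_mm) / 1000
  half <- seq(0, 1.5 * w, by = grid_mm)
  x <- c(-rev(half[-1L]), half)       # exactly symmetric grid
  f <- profile_fun(beam, field_cm, depth_mm, ssd_cm)
  scan_curve(axis = axis, positions = x, values = f(x),
             detector_id = detector_id, field_x_cm = field_cm,
             field_y_cm = field_cm, ssd_cm = ssd_cm,
             scan_depth_mm = depth_mm)
}

#' Synthetic depth-dose curve
#'
#' Bi-exponential build-up/attenuation model normalised to 100 at its
#' closed-form maximum.
#'
#' @param beam A [beam_model()].
#' @param field_cm Collimator side (cm); metadata only (the synthetic depth
#'   dose shape is field-size independent).
#' @param depths_mm Increasing depths (mm) to sample.
#' @param detector_id Label for the emitted curve.
#' @return A [scan_curve()] flagged `max100`.
#' @export
true_pdd <- function(beam, field_cm, depths_mm = seq(0, 310, by = 0.5),
                     detector_id = "point") {
  stopifnot(inherits(beam, "beam_model"))
  a <- beam$buildup_per_mm; mu <- beam$mu_per_mm
  shape <- function(d) (1 - exp(-a * d)) * exp(-mu * d)
  dmax <- log(1 + a / mu) / a
  vals <- 100 * shape(depths_mm) / shape(dmax)
  scan_curve(axis = "depth", positions = depths_mm, values = vals,
             detector_id = detector_id, field_x_cm = field_cm,
             field_y_cm = field_cm, normalized = "max100")
}

#' Detector response model
#'
#' How a real detector's reading ratio deviates from the true output
#' factor: a 1-D top-hat volume-averaging aperture along the scan axis plus
#' a signed exponential over/under-response
#' `r(S) = VA(S) * (1 + beta * exp(-S/tau))`, normalised so `r(msr) = 1`.
#' `beta > 0` emulates a shielded diode (scatter from the dense
#' encapsulation), `beta < 0` an unshielded diode's energy-dependent
#' under-response at small sizes, `beta ~ 0` ionisation chambers whose small-
#' field deficit is dominated by volume averaging.
#'
#' @param detector_id Label.
#' @param kind One of `"microchamber"`, `"shielded_diode"`,
#'   `"unshielded_diode"`, `"reference_chamber"`.
#' @param aperture_mm Sensitive-dimension width of the volume-averaging
#'   top-hat (0 for a point detector).
#' @param beta,tau_cm Over/under-response amplitude and field-size scale.
#' @return An object of class `detector_model`.
#' @export
detector_model <- function(detector_id,
                           kind = c("microchamber", "shielded_diode",
                                    "unshielded_diode", "reference_chamber"),
                           aperture_mm = 0, beta = 0, tau_cm = 2) {
  kind <- match.arg(kind)
  if (aperture_mm < 0) {
    stop_sf("aperture_mm must be non-negative", "sfdose_argument_error")
  }
  check_positive(tau_cm, "tau_cm")
  structure(list(detector_id = as.character(detector_id), kind = kind,
                 aperture_mm = aperture_mm, beta = beta, tau_cm = tau_cm),
            class = "detector_model")
}

#' Default synthetic detector set
#'
#' Four detectors mirroring a typical small-field commissioning kit: a
#' micro ionisation chamber (3.6 mm cavity length along the scan axis), a
#' shielded and an unshielded diode (2.0 mm sensitive diameter) and an
#' ideal reference chamber used only at intermediate/reference sizes.
#' Response parameters are calibrated so the uncorrected cross-detector
#' spread at a 1 cm field falls in the few-percent regime observed with
#' real detector sets.
#'
#' @return Named list of [detector_model()] objects.
#' @export
default_detectors <- function() {
  list(
    CC01 = detector_model("CC01", "microchamber", aperture_mm = 3.6,
                          beta = 0, tau_cm = 2),
    PFD = detector_model("PFD", "shielded_diode", aperture_mm = 2.0,
                         beta = 0.13, tau_cm = 2),
    EFD = detector_model("EFD", "unshielded_diode", aperture_mm = 2.0,
                         beta = -0.034, tau_cm = 2),
    REF = detector_model("REF", "reference_chamber", aperture_mm = 0,
                         beta = 0, tau_cm = 2)
  )
}

# Mean of the closed-form profile over the detector aperture centred on the
# axis, relative to the central value (composite Simpson, fixed 81 points —
# deterministic).
volume_averaging <- function(det, beam, field_cm, depth_mm = 100,
                             ssd_cm = 100) {
  if (det$aperture_mm <= 0) return(rep(1, length(field_cm)))
  vapply(field_cm, function(S) {
    f <- profile_fun(beam, S, depth_mm, ssd_cm)
    n <- 81L
    x <- seq(-det$aperture_mm / 2, det$aperture_mm / 2, length.out = n)
    wts <- c(1, rep(c(4, 2), length.out = n - 2L), 1)
    mean_val <- sum(wts * f(x)) / sum(wts)
    mean_val / f(0)
  }, 0)
}

#' Simulated detector response ratio
#'
#' `r(S)`: the detector's reading per unit dose at field side `S`, relative
#' to the msr field (`r(msr) = 1`). An uncorrected reading-ratio output
#' factor of this detector equals `Omega_true(S) * r(S)`.
#'
#' @param det A [detector_model()].
#' @param beam A [beam_model()].
#' @param sclin_cm Field side(s), cm.
#' @param depth_mm Measurement depth, mm (default 100).
#' @return Normalised response ratio(s).
#' @export
detector_response <- function(det, beam, sclin_cm, depth_mm = 100) {
  stopifnot(inherits(det, "detector_model"), inherits(beam, "beam_model"))
  check_positive(sclin_cm, "sclin_cm")
  raw <- function(S) {
    volume_averaging(det, beam, S, depth_mm) *
      (1 + det$beta * exp(-S / det$tau_cm))
  }
  raw(sclin_cm) / raw(beam$msr_cm)
}

#' Output correction factor implied by the response model
#'
#' Exact reciprocal of the normalised response: applying it to this
#' detector's reading ratio recovers the true output factor identically.
#'
#' @inheritParams detector_response
#' @return Implied correction factor(s).
#' @export
implied_k <- function(det, beam, sclin_cm, depth_mm = 100) {
  1 / detector_response(det, beam, sclin_cm, depth_mm)
}

#' Simulate repeated electrometer readings
#'
#' Readings are `Omega_true(S) * r(S) * (1 + eps)` with iid Gaussian
#' relative noise, in arbitrary units where the zero-noise msr reading is 1.
#' Uses the current RNG state; seed at the scenario level for
#' reproducibility.
#'
#' @param det A [detector_model()].
#' @param beam A [beam_model()].
#' @param field_cm Collimator side, cm.
#' @param noise_sd Relative reading noise SD (default 0.003).
#' @param n_repeats Number of repeats (default 3).
#' @param defined_by `"jaw"` or `"mlc"` (metadata).
#' @return A [reading_set()].
#' @export
simulate_readings <- function(det, beam, field_cm, noise_sd = 0.003,
                              n_repeats = 3L, defined_by = "jaw") {
  stopifnot(inherits(det, "detector_model"), inherits(beam, "beam_model"))
  if (noise_sd < 0) stop_sf("noise_sd must be >= 0", "sfdose_argument_error")
  truth <- true_fof(beam, field_cm) * detector_response(det, beam, field_cm)
  eps <- if (noise_sd > 0) stats::rnorm(n_repeats, 0, noise_sd)
         else rep(0, n_repeats)
  reading_set(det$detector_id,
              field_geometry(collimator_x_cm = field_cm,
                             defined_by = defined_by),
              truth * (1 + eps))
}

#' Generate a complete synthetic commissioning scenario
#'
#' Emits, under `out_dir`: per-field scan files with cross-plane and
#' in-plane point-detector profiles at the measurement depth, a depth-dose
#' scan file, a readings CSV for every detector and field, a correction
#' factor table CSV, and `truth.json` recording the ground truth. The
#' correction factor tables are indexed by the dosimetric equivalent square
#' size `S_clin` measured from the emitted profiles themselves — exactly
#' how protocol tables are indexed — with values implied by each detector's
#' response model, so the full pipeline closes on the true output factors.
#' All numerics are printed with round-trip-exact precision; rerunning with
#' the same seed reproduces every file byte for byte.
#'
#' @param config Optional list overriding defaults: `fields` (cm, default
#'   `c(1, 2, 3, 4, 6, 10)`), `detectors` (list of [detector_model()]),
#'   `beam` (a [beam_model()]), `noise_sd` (default 0.003), `n_repeats`
#'   (default 3), `grid_mm` (default 0.2), `depth_mm` (default 100),
#'   `ssd_cm` (default 100), `pdd_grid_mm` (default 0.5).
#' @param seed Integer seed controlling all randomness.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a `synthetic_scenario` list: `manifest` (emitted file
#'   paths), `geometries` (side vs measured `S_clin`), `truth` (true output
#'   factors, implied k, widths), and the resolved `config`.
#' @export
generate_scenario <- function(config = list(), seed = 1L, out_dir) {
  cfg <- utils::modifyList(list(
    fields = c(1, 2, 3, 4, 6, 10), detectors = default_detectors(),
    beam = beam_model(), noise_sd = 0.003, n_repeats = 3L,
    grid_mm = 0.2, depth_mm = 100, ssd_cm = 100, pdd_grid_mm = 0.5
  ), config)
  beam <- cfg$beam
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_sf(sprintf("cannot create %s", out_dir), "sfdose_io_error")
  }
  set.seed(as.integer(seed))
  manifest <- character()

  # --- profiles and measured S_clin -------------------------------------
  geoms <- data.frame(side_cm = numeric(), sclin_cm = numeric(),
                      fwhm_cross_mm = numeric(), fwhm_in_mm = numeric())
  for (S in cfg$fields) {
    cross <- true_profile(beam, S, cfg$depth_mm, cfg$ssd_cm, "crossline",
                          cfg$grid_mm)
    inpl <- true_profile(beam, S, cfg$depth_mm, cfg$ssd_cm, "inline",
                         cfg$grid_mm)
    path <- file.path(out_dir, sprintf("profiles_%gcm.scan", S))
    write_scan_table(scan_set(list(cross, inpl)), path)
    manifest <- c(manifest, path)
    geo <- sclin_from_profiles(cross, inpl)
    geoms <- rbind(geoms, data.frame(
      side_cm = S, sclin_cm = geo$sclin_cm,
      fwhm_cross_mm = geo$fwhm_cross_cm * 10,
      fwhm_in_mm = geo$fwhm_in_cm * 10))
  }

  pdd_path <- file.path(out_dir, "pdd.scan")
  write_scan_table(true_pdd(beam, beam$msr_cm,
                            seq(0, 310, by = cfg$pdd_grid_mm)), pdd_path)
  manifest <- c(manifest, pdd_path)

  # --- readings ----------------------------------------------------------
  rows <- list()
  for (det in cfg$detectors) {
    for (S in cfg$fields) {
      rs <- simulate_readings(det, beam, S, cfg$noise_sd, cfg$n_repeats)
      rows[[length(rows) + 1L]] <- data.frame(
        detector = det$detector_id, field_side_cm = S, defined_by = "jaw",
        "repeat" = seq_len(cfg$n_repeats), reading = rs$readings,
        check.names = FALSE)
    }
  }
  readings_df <- do.call(rbind, rows)
  readings_path <- file.path(out_dir, "readings.csv")
  writeLines(c("detector,field_side_cm,defined_by,repeat,reading",
               sprintf("%s,%s,%s,%d,%s", readings_df$detector,
                       fmt_num(readings_df$field_side_cm),
                       readings_df$defined_by, readings_df$`repeat`,
                       fmt_num(readings_df$reading))), readings_path)
  manifest <- c(manifest, readings_path)

  # --- implied correction factor tables, indexed by measured S_clin ------
  krows <- list()
  for (det in cfg$detectors) {
    k_vals <- implied_k(det, beam, cfg$fields, cfg$depth_mm)
    ord <- order(geoms$sclin_cm)
    krows[[length(krows) + 1L]] <- data.frame(
      detector_model = det$detector_id,
      sclin_cm = geoms$sclin_cm[ord], k = k_vals[ord])
  }
  kdf <- do.call(rbind, krows)
  ktable_path <- file.path(out_dir, "ktable.csv")
  writeLines(c("detector_model,sclin_cm,k",
               sprintf("%s,%s,%s", kdf$detector_model, fmt_num(kdf$sclin_cm),
                       fmt_num(kdf$k))), ktable_path)
  manifest <- c(manifest, ktable_path)

  # --- truth record ------------------------------------------------------
  truth <- list(
    seed = as.integer(seed),
    beam = beam[c("energy", "tpr2010", "dmax_mm", "mu_per_mm",
                  "buildup_per_mm", "sigma_mm", "w0_cm", "c_occ", "c1",
                  "lambda_cm", "msr_cm")],
    fields_cm = cfg$fields,
    omega_true = stats::setNames(as.list(true_fof(beam, cfg$fields)),
                                 paste0("S", cfg$fields)),
    geometries = geoms,
    implied_k = lapply(stats::setNames(cfg$detectors,
                                       vapply(cfg$detectors,
                                              function(d) d$detector_id, "")),
                       function(d) stats::setNames(
                         as.list(implied_k(d, beam, cfg$fields, cfg$depth_mm)),
                         paste0("S", cfg$fields)))
  )
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- c(manifest, truth_path)

  invisible(structure(
    list(manifest = manifest, geometries = geoms, truth = truth,
         config = cfg, out_dir = out_dir),
    class = "synthetic_scenario"))
}

#' Simulate a finite-aperture detector scan of a profile
#'
#' Convolves a profile with a centred top-hat of the detector's sensitive
#' width (the 1-D volume-averaging model): each output sample is the mean of
#' the profile's linear interpolant across the aperture. Symmetric
#' non-negative apertures can only broaden the penumbra.
#'
#' @param curve A lateral [scan_curve()].
#' @param width_mm Aperture width (0 returns the curve unchanged).
#' @param n_sub Odd number of sub-samples across the aperture (default 33).
#' @return The convolved [scan_curve()].
#' @export
convolve_aperture <- function(curve, width_mm, n_sub = 33L) {
  stopifnot(inherits(curve, "scan_curve"))
  if (width_mm < 0) {
    stop_sf("width_mm must be non-negative", "sfdose_argument_error")
  }
  if (width_mm == 0) return(curve)
  n_sub <- as.integer(n_sub)
  if (n_sub %% 2L == 0L) n_sub <- n_sub + 1L
  offs <- seq(-width_mm / 2, width_mm / 2, length.out = n_sub)
  wts <- c(1, rep(c(4, 2), length.out = n_sub - 2L), 1)  # Simpson
  x <- curve$positions
  acc <- numeric(length(x))
  for (j in seq_along(offs)) {
    acc <- acc + wts[j] *
      stats::approx(x, curve$values, xout = x + offs[j], rule = 2)$y
  }
  curve$values <- acc / sum(wts)
  curve$normalized <- "raw"
  curve
}

#' Repeated-noise study: does correction shrink the detector spread?
#'
#' Monte Carlo replication of the cross-detector %SD comparison: at one
#' clinical field size, simulate noisy reading sets for each detector,
#' compute the uncorrected %SD across detectors and the %SD after applying
#' each detector's implied correction factor, and count how often
#' correction reduces the spread.
#'
#' @param beam A [beam_model()].
#' @param detectors List of [detector_model()] to pool (the zero-aperture
#'   reference chamber is excluded automatically).
#' @param field_cm Clinical field side, cm (default 1).
#' @param noise_sd Relative reading noise SD (default 0.003).
#' @param n_repeats Readings per set (default 3).
#' @param n_replicates Number of Monte Carlo replicates (default 200).
#' @param seed Integer seed.
#' @return List: `fraction_improved`, `mean_percent_sd_uncorrected`,
#'   `mean_percent_sd_corrected`, `n_replicates`.
#' @export
replicate_correction_study <- function(beam = beam_model(),
                                       detectors = default_detectors(),
                                       field_cm = 1, noise_sd = 0.003,
                                       n_repeats = 3L, n_replicates = 200L,
                                       seed = 1L) {
  detectors <- Filter(function(d) d$kind != "reference_chamber", detectors)
  if (length(detectors) < 2L) {
    stop_sf("at least 2 non-reference detectors are required",
            "sfdose_argument_error")
  }
  set.seed(as.integer(seed))
  omega <- true_fof(beam, field_cm)
  r <- vapply(detectors, function(d) detector_response(d, beam, field_cm), 0)
  k <- 1 / r
  psd_u <- psd_c <- numeric(n_replicates)
  for (b in seq_len(n_replicates)) {
    u <- vapply(seq_along(detectors), function(i) {
      clin <- omega * r[i] * (1 + stats::rnorm(n_repeats, 0, noise_sd))
      msr <- 1 * (1 + stats::rnorm(n_repeats, 0, noise_sd))
      mean(clin) / mean(msr)
    }, 0)
    psd_u[b] <- percent_sd(u)
    psd_c[b] <- percent_sd(u * k)
  }
  list(fraction_improved = mean(psd_c < psd_u),
       mean_percent_sd_uncorrected = mean(psd_u),
       mean_percent_sd_corrected = mean(psd_c),
       n_replicates = n_replicates)
}
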