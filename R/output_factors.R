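#' Repeated point readings for one detector and field
#'
#' Electrometer readings (consistent arbitrary units) collected with one
#' detector in one field. A coefficient of variation above 1% is flagged
#' with a warning, as is customary for charge-collection repeats.
#'
#' @param detector_id Detector label.
#' @param field A [field_geometry()], or a bare numeric collimator side (cm)
#'   which is promoted to a square-field geometry.
#' @param readings Numeric vector of positive readings (at least one).
#' @param environment Optional metadata list (temperature, pressure, ...).
#' @return An object of class `reading_set`.
#' @export
reading_set <- function(detector_id, field, readings, environment = list()) {
  if (is.numeric(field) && length(field) == 1L) {
    field <- field_geometry(collimator_x_cm = field)
  }
  stopifnot(inherits(field, "field_geometry"))
  readings <- as.numeric(readings)
  if (!length(readings)) {
    stop_sf("at least one reading is required", "sfdose_validation_error")
  }
  check_positive(readings, "readings")
  cv <- if (length(readings) > 1L) {
    stats::sd(readings) / mean(readings)
  } else 0
  if (cv > 0.01) {
    warn_sf(sprintf(
      "reading set %s: coefficient of variation %.2f%% exceeds 1%%",
      detector_id, 100 * cv), "sfdose_cv_warning")
  }
  structure(list(detector_id = as.character(detector_id), field = field,
                 readings = readings, cv = cv, environment = environment),
            class = "reading_set")
}

#' Uncorrected field output factor
#'
#' Ratio of the mean detector reading in the clinical field to the mean
#' reading in the machine-specific reference (msr) field. Readings are
#' averaged before ratioing.
#'
#' @param clin [reading_set()] at the clinical field.
#' @param msr [reading_set()] at the msr field; same detector.
#' @return The uncorrected output factor (a reading ratio).
#' @export
uncorrected_fof <- function(clin, msr) {
  stopifnot(inherits(clin, "reading_set"), inherits(msr, "reading_set"))
  if (clin$detector_id != msr$detector_id) {
    stop_sf(sprintf("detector mismatch: '%s' vs '%s'",
                    clin$detector_id, msr$detector_id),
            "sfdose_consistency_error")
  }
  mean(clin$readings) / mean(msr$readings)
}

#' Empirical output correction factor from a known dose ratio
#'
#' The correction factor is the true dose ratio divided by the measured
#' reading ratio: it converts what a detector reports into what the beam
#' delivers.
#'
#' @param dose_ratio True field output factor (dose ratio).
#' @param reading_ratio Measured uncorrected output factor.
#' @return `dose_ratio / reading_ratio`.
#' @export
derive_k <- function(dose_ratio, reading_ratio) {
  check_positive(dose_ratio, "dose_ratio")
  check_positive(reading_ratio, "reading_ratio")
  dose_ratio / reading_ratio
}

#' Output correction factor table for one detector model
#'
#' Protocol-style table of correction factors `k` indexed by equivalent
#' square field side `S_clin` (cm), with a piecewise-linear interpolation
#' contract.
#'
#' @param detector_model Detector model label.
#' @param sclin_cm Strictly increasing abscissae (cm).
#' @param k Positive correction factors, same length.
#' @param source Free-text provenance of the values (protocol table, derived
#'   from a response model, ...).
#' @return An object of class `k_factor_table`.
#' @export
k_factor_table <- function(detector_model, sclin_cm, k, source = "") {
  sclin_cm <- as.numeric(sclin_cm); k <- as.numeric(k)
  if (!length(sclin_cm) || length(sclin_cm) != length(k)) {
    stop_sf("sclin_cm and k must be non-empty and of equal length",
            "sfdose_validation_error")
  }
  if (any(diff(sclin_cm) <= 0)) {
    stop_sf("sclin_cm must be strictly increasing", "sfdose_validation_error")
  }
  check_positive(k, "k")
  structure(list(detector_model = as.character(detector_model),
                 points = data.frame(sclin_cm = sclin_cm, k = k),
                 source = source),
            class = "k_factor_table")
}

#' @export
print.k_factor_table <- function(x, ...) {
  cat(sprintf("<k_factor_table> %s: %d points on S_clin [%g, %g] cm\n",
              x$detector_model, nrow(x$points),
              min(x$points$sclin_cm), max(x$points$sclin_cm)))
  invisible(x)
}

#' Interpolate an output correction factor at a field size
#'
#' Piecewise-linear interpolation in `S_clin`, exact at the table knots.
#' Queries outside the tabulated range are an error by default:
#' extrapolating `k` below the smallest tabulated field is precisely the
#' failure mode correction protocols warn against. With `clamp = TRUE` the
#' endpoint value is returned with a warning instead.
#'
#' @param table A [k_factor_table()].
#' @param sclin_cm Query field side(s), cm.
#' @param clamp Return the endpoint value (with a warning) outside the range
#'   instead of failing. Default `FALSE`.
#' @return Interpolated correction factor(s).
#' @export
interpolate_k <- function(table, sclin_cm, clamp = FALSE) {
  stopifnot(inherits(table, "k_factor_table"))
  check_positive(sclin_cm, "sclin_cm")
  p <- table$points
  lo <- p$sclin_cm[1L]; hi <- p$sclin_cm[nrow(p)]
  out_of_range <- sclin_cm < lo | sclin_cm > hi
  if (any(out_of_range)) {
    if (!clamp) {
      stop_sf(sprintf(
        "S_clin %s cm outside tabulated range [%g, %g] cm for %s",
        paste(signif(sclin_cm[out_of_range], 6), collapse = ", "),
        lo, hi, table$detector_model), "sfdose_range_error")
    }
    warn_sf(sprintf("S_clin clamped to tabulated range [%g, %g] cm", lo, hi),
            "sfdose_clamp_warning")
  }
  if (nrow(p) == 1L) return(rep(p$k, length(sclin_cm)))
  stats::approx(p$sclin_cm, p$k, xout = pmin(pmax(sclin_cm, lo), hi),
                method = "linear", ties = "ordered")$y
}

#' Corrected field output factor
#'
#' Applies an output correction factor to an uncorrected (reading-ratio)
#' output factor, giving the dose-ratio field output factor.
#'
#' @param uncorrected Uncorrected output factor (reading ratio).
#' @param k Output correction factor.
#' @return `uncorrected * k`.
#' @export
corrected_fof <- function(uncorrected, k) {
  check_positive(uncorrected, "uncorrected")
  check_positive(k, "k")
  uncorrected * k
}

#' Intermediate field method (daisy-chained) output factor
#'
#' Links a small-field detector to a reference ionisation chamber through an
#' intermediate field, so each detector is used only over the field range
#' where it is reliable: the small-field detector carries the clinical-to-
#' intermediate step and the chamber the intermediate-to-msr step, each with
#' its own correction factor.
#'
#' @param m_clin_det Small-field detector reading at the clinical field.
#' @param m_int_det Small-field detector reading at the intermediate field.
#' @param k_det_clin_int Correction factor for the detector between clinical
#'   and intermediate fields.
#' @param m_int_ic Reference chamber reading at the intermediate field.
#' @param m_msr_ic Reference chamber reading at the msr field.
#' @param k_ic_int_msr Correction factor for the chamber between intermediate
#'   and msr fields.
#' @return The daisy-chained field output factor.
#' @export
ifm_fof <- function(m_clin_det, m_int_det, k_det_clin_int,
                    m_int_ic, m_msr_ic, k_ic_int_msr) {
  for (nm in c("m_clin_det", "m_int_det", "k_det_clin_int",
               "m_int_ic", "m_msr_ic", "k_ic_int_msr")) {
    check_positive(get(nm), nm)
  }
  (m_clin_det / m_int_det) * k_det_clin_int *
    (m_int_ic / m_msr_ic) * k_ic_int_msr
}

#' Advisory small-field flag
#'
#' A field is flagged "small" when its equivalent square side falls below a
#' configured threshold (loss of lateral charged-particle equilibrium sets
#' in below a beam-quality-dependent radius; the threshold is a user choice,
#' 2 cm by default). Strict inequality: the boundary is not flagged.
#'
#' @param sclin_cm Equivalent square field side, cm.
#' @param threshold_cm Threshold side, cm (default 2).
#' @return Logical: `sclin_cm < threshold_cm`.
#' @export
small_field_flag <- function(sclin_cm, threshold_cm = 2) {
  check_positive(sclin_cm, "sclin_cm")
  check_positive(threshold_cm, "threshold_cm")
  sclin_cm < threshold_cm
}

#' Build a field output factor table for one detector
#'
#' Assembles per-field uncorrected and corrected output factors from a
#' detector's reading sets. Under `method = "direct"` each clinical field is
#' corrected with `k` interpolated at its `S_clin`. Under `method = "ifm"`
#' the chain runs through an intermediate field: the detector covers
#' clinical-to-intermediate (with the ratio of its interpolated k values)
#' and a reference chamber covers intermediate-to-msr.
#'
#' @param readings List of [reading_set()] for one detector, covering every
#'   clinical field and the msr field.
#' @param geometries Data frame mapping `side_cm` (collimator side at
#'   100 cm) to `sclin_cm` (measured equivalent square side).
#' @param k_table [k_factor_table()] for this detector.
#' @param method `"direct"` or `"ifm"`.
#' @param msr_side_cm Collimator side of the msr field (default 10).
#' @param ifm_config For `method = "ifm"`: list with `int_side_cm`
#'   (intermediate field side, default 4), `ic_readings` (list of
#'   [reading_set()] for the reference chamber at the intermediate and msr
#'   fields) and `ic_k_table` (its [k_factor_table()]).
#' @param small_field_threshold_cm Threshold for the advisory small-field
#'   flag (default 2).
#' @return A data frame of class `fof_table` with columns
#'   `collimator_side_cm`, `sclin_cm`, `fof_uncorrected`, `k_applied`,
#'   `fof_corrected`, `method`, `small_field`; attribute `detector_id`.
#' @export
build_fof_table <- function(readings, geometries, k_table,
                            method = c("direct", "ifm"),
                            msr_side_cm = 10, ifm_config = NULL,
                            small_field_threshold_cm = 2) {
  method <- match.arg(method)
  stopifnot(is.list(readings),
            all(vapply(readings, inherits, TRUE, "reading_set")),
            inherits(k_table, "k_factor_table"),
            is.data.frame(geometries),
            all(c("side_cm", "sclin_cm") %in% names(geometries)))
  dets <- unique(vapply(readings, function(r) r$detector_id, ""))
  if (length(dets) != 1L) {
    stop_sf("readings mix detectors; build one table per detector",
            "sfdose_consistency_error")
  }
  sides <- vapply(readings, function(r) r$field$collimator_x_cm, 0)
  i_msr <- which(abs(sides - msr_side_cm) < 1e-9)
  if (length(i_msr) != 1L) {
    stop_sf(sprintf("exactly one msr (%g cm) reading set is required",
                    msr_side_cm), "sfdose_configuration_error")
  }
  msr <- readings[[i_msr]]

  sclin_of <- function(side) {
    j <- which(abs(geometries$side_cm - side) < 1e-9)
    if (length(j) != 1L) {
      stop_sf(sprintf("no S_clin geometry for the %g cm field", side),
              "sfdose_configuration_error")
    }
    geometries$sclin_cm[j]
  }

  if (method == "ifm") {
    if (is.null(ifm_config)) ifm_config <- list()
    int_side <- ifm_config$int_side_cm %||% 4
    ic_readings <- ifm_config$ic_readings
    ic_k_table <- ifm_config$ic_k_table
    if (is.null(ic_readings) || is.null(ic_k_table)) {
      stop_sf("ifm method needs ic_readings and ic_k_table in ifm_config",
              "sfdose_configuration_error")
    }
    i_int <- which(abs(sides - int_side) < 1e-9)
    if (length(i_int) != 1L) {
      stop_sf(sprintf(
        "detector readings at the intermediate field (%g cm) are required",
        int_side), "sfdose_configuration_error")
    }
    ic_sides <- vapply(ic_readings, function(r) r$field$collimator_x_cm, 0)
    j_int <- which(abs(ic_sides - int_side) < 1e-9)
    j_msr <- which(abs(ic_sides - msr_side_cm) < 1e-9)
    if (length(j_int) != 1L || length(j_msr) != 1L) {
      stop_sf("chamber readings at the intermediate and msr fields are required",
              "sfdose_configuration_error")
    }
    sclin_int <- sclin_of(int_side)
    sclin_msr <- sclin_of(msr_side_cm)
    # chamber leg: intermediate -> msr, corrected with the chamber's own k
    # ratio (k at msr is 1 by construction of protocol tables; the ratio
    # form keeps the chain exact even if the table is normalised elsewhere)
    k_ic <- interpolate_k(ic_k_table, sclin_int) /
            interpolate_k(ic_k_table, sclin_msr)
    ic_leg <- mean(ic_readings[[j_int]]$readings) /
              mean(ic_readings[[j_msr]]$readings)
    m_int_det <- mean(readings[[i_int]]$readings)
  }

  ord <- order(sides)
  rows <- lapply(ord, function(i) {
    side <- sides[i]
    scl <- sclin_of(side)
    u <- uncorrected_fof(readings[[i]], msr)
    if (abs(side - msr_side_cm) < 1e-9) {
      fofc <- 1; k <- 1; u <- 1; meth <- method
    } else if (method == "direct") {
      k <- interpolate_k(k_table, scl)
      fofc <- corrected_fof(u, k)
      meth <- "direct"
    } else {
      k <- interpolate_k(k_table, scl) / interpolate_k(k_table, sclin_int)
      fofc <- ifm_fof(mean(readings[[i]]$readings), m_int_det, k,
                      ic_leg * 1, 1, k_ic)  # chamber leg precomputed as ratio
      meth <- "ifm"
    }
    data.frame(collimator_side_cm = side, sclin_cm = scl,
               fof_uncorrected = u, k_applied = k, fof_corrected = fofc,
               method = meth,
               small_field = small_field_flag(scl, small_field_threshold_cm))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$collimator_side_cm), , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$fof_corrected <= 0 | out$fof_corrected > 1.2)) {
    stop_sf("corrected output factors outside (0, 1.2]",
            "sfdose_validation_error")
  }
  # physical FOFs grow with field size; violations are suspicious, not fatal
  if (any(diff(rev(out$fof_corrected)) < -1e-12)) {
    warn_sf(sprintf("corrected FOFs of %s are not monotone in field size",
                    dets), "sfdose_monotonicity_warning")
  }
  attr(out, "detector_id") <- dets
  class(out) <- c("fof_table", class(out))
  out
}

#' Read a readings CSV
#'
#' Columns: `detector,field_side_cm,defined_by,repeat,reading`.
#'
#' @param path CSV file path.
#' @return Named list (by detector) of lists of [reading_set()] (one per
#'   field side).
#' @export
read_readings <- function(path) {
  if (!file.exists(path)) {
    stop_sf(sprintf("readings file not found: %s", path), "sfdose_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "repeat."] <- "repeat_idx"  # `repeat` is reserved
  need <- c("detector", "field_side_cm", "defined_by", "reading")
  if (!all(need %in% names(df))) {
    stop_sf(sprintf("readings file must have columns %s",
                    paste(need, collapse = ", ")), "sfdose_parse_error")
  }
  out <- list()
  for (det in unique(df$detector)) {
    sub <- df[df$detector == det, , drop = FALSE]
    sets <- lapply(sort(unique(sub$field_side_cm), decreasing = TRUE),
                   function(s) {
      rows <- sub[sub$field_side_cm == s, , drop = FALSE]
      reading_set(det,
                  field_geometry(collimator_x_cm = s,
                                 defined_by = rows$defined_by[1]),
                  rows$reading)
    })
    out[[det]] <- sets
  }
  out
}

#' Read an output correction factor table CSV
#'
#' Columns: `detector_model,sclin_cm,k`; one or more detector models per
#' file.
#'
#' @param path CSV file path.
#' @return Named list of [k_factor_table()] by detector model.
#' @export
read_k_table <- function(path) {
  if (!file.exists(path)) {
    stop_sf(sprintf("k-table file not found: %s", path), "sfdose_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("detector_model", "sclin_cm", "k")
  if (!all(need %in% names(df))) {
    stop_sf(sprintf("k-table file must have columns %s",
                    paste(need, collapse = ", ")), "sfdose_parse_error")
  }
  out <- list()
  for (det in unique(df$detector_model)) {
    sub <- df[df$detector_model == det, , drop = FALSE]
    sub <- sub[order(sub$sclin_cm), , drop = FALSE]
    out[[det]] <- k_factor_table(det, sub$sclin_cm, sub$k,
                                 source = basename(path))
  }
  out
}
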