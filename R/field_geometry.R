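#' Field geometry descriptor
#'
#' Collimator setting plus, once measured, the dosimetric field widths and
#' the equivalent square field side `S_clin` used to index output correction
#' factor tables.
#'
#' @param collimator_x_cm,collimator_y_cm Collimator setting (cm) at 100 cm.
#' @param defined_by `"jaw"` or `"mlc"`.
#' @param ssd_cm Source-surface distance (cm).
#' @param measurement_depth_mm Depth of the width measurement (mm).
#' @param fwhm_cross_cm,fwhm_in_cm Dosimetric widths at depth (cm), optional
#'   until measured.
#' @param sclin_cm Equivalent square side (cm), optional until computed; must
#'   lie between the two widths when present.
#' @return An object of class `field_geometry`.
#' @export
field_geometry <- function(collimator_x_cm, collimator_y_cm = collimator_x_cm,
                           defined_by = c("jaw", "mlc"), ssd_cm = 100,
                           measurement_depth_mm = 100,
                           fwhm_cross_cm = NA_real_, fwhm_in_cm = NA_real_,
                           sclin_cm = NA_real_) {
  defined_by <- match.arg(defined_by)
  for (nm in c("collimator_x_cm", "collimator_y_cm", "ssd_cm",
               "measurement_depth_mm")) {
    check_positive(get(nm), nm)
  }
  if (!is.na(sclin_cm) && !is.na(fwhm_cross_cm) && !is.na(fwhm_in_cm)) {
    lo <- min(fwhm_cross_cm, fwhm_in_cm) - 1e-9
    hi <- max(fwhm_cross_cm, fwhm_in_cm) + 1e-9
    if (sclin_cm < lo || sclin_cm > hi) {
      stop_sf("sclin_cm must lie between the two measured widths",
              "sfdose_validation_error")
    }
  }
  structure(
    list(collimator_x_cm = collimator_x_cm, collimator_y_cm = collimator_y_cm,
         defined_by = defined_by, ssd_cm = ssd_cm,
         measurement_depth_mm = measurement_depth_mm,
         fwhm_cross_cm = fwhm_cross_cm, fwhm_in_cm = fwhm_in_cm,
         sclin_cm = sclin_cm),
    class = "field_geometry")
}

#' @export
print.field_geometry <- function(x, ...) {
  cat(sprintf(
    "<field_geometry> %g x %g cm (%s) at SSD %g cm, depth %g mm",
    x$collimator_x_cm, x$collimator_y_cm, x$defined_by, x$ssd_cm,
    x$measurement_depth_mm))
  if (!is.na(x$sclin_cm)) {
    cat(sprintf("; widths %0.2f/%0.2f cm, S_clin %0.2f cm",
                x$fwhm_cross_cm, x$fwhm_in_cm, x$sclin_cm))
  }
  cat("\n")
  invisible(x)
}

#' Project a length along the beam divergence
#'
#' Scales a lateral length defined at one source distance to another by the
#' ratio of distances (e.g. a 6 cm collimator side at 100 cm projects to
#' 6.6 cm at the 110 cm measurement plane of a 100 cm SSD, 10 cm depth setup).
#'
#' @param length_cm Length at `ref_cm`.
#' @param ref_cm Distance at which `length_cm` is defined.
#' @param target_cm Distance to project to.
#' @return Length at `target_cm`.
#' @export
project_length <- function(length_cm, ref_cm, target_cm) {
  check_positive(length_cm, "length_cm")
  check_positive(ref_cm, "ref_cm")
  check_positive(target_cm, "target_cm")
  length_cm * target_cm / ref_cm
}

#' Equivalent square field side
#'
#' Geometric mean of the cross-plane and in-plane dosimetric field widths,
#' the protocol definition of the equivalent square small-field size
#' `S_clin`.
#'
#' @param A_cm Cross-plane FWHM (cm) at the measurement plane.
#' @param B_cm In-plane FWHM (cm) at the measurement plane.
#' @return `sqrt(A_cm * B_cm)`, symmetric in its arguments.
#' @export
equivalent_square <- function(A_cm, B_cm) {
  check_positive(A_cm, "A_cm")
  check_positive(B_cm, "B_cm")
  sqrt(A_cm * B_cm)
}

#' Equivalent square field size from a pair of measured profiles
#'
#' Normalises, recentres and measures the FWHM of a cross-plane and an
#' in-plane profile of the same field, converts the widths to cm at the
#' measurement plane, and fills in `S_clin`. No back-projection to the
#' isocentre plane is applied: `S_clin` is defined at the plane where the
#' widths were measured.
#'
#' @param cross Cross-plane (crossline) lateral [scan_curve()].
#' @param inplane In-plane (inline) lateral [scan_curve()].
#' @param defined_by `"jaw"` or `"mlc"`.
#' @return A [field_geometry()] with widths and `sclin_cm` filled in.
#' @export
sclin_from_profiles <- function(cross, inplane, defined_by = "jaw") {
  stopifnot(inherits(cross, "scan_curve"), inherits(inplane, "scan_curve"))
  if (cross$axis == "depth" || inplane$axis == "depth") {
    stop_sf("both curves must be lateral profiles", "sfdose_argument_error")
  }
  same <- function(a, b) (is.na(a) && is.na(b)) || isTRUE(all.equal(a, b))
  if (!same(cross$field_x_cm, inplane$field_x_cm) ||
      !same(cross$field_y_cm, inplane$field_y_cm) ||
      !same(cross$scan_depth_mm, inplane$scan_depth_mm) ||
      !same(cross$ssd_cm, inplane$ssd_cm)) {
    stop_sf("cross and in-plane profiles describe different fields",
            "sfdose_consistency_error")
  }
  measure <- function(p) fwhm(normalize_to_cax(recenter(p))) / 10  # mm -> cm
  A <- measure(cross)
  B <- measure(inplane)
  field_geometry(
    collimator_x_cm = cross$field_x_cm, collimator_y_cm = cross$field_y_cm,
    defined_by = defined_by, ssd_cm = cross$ssd_cm,
    measurement_depth_mm = cross$scan_depth_mm,
    fwhm_cross_cm = A, fwhm_in_cm = B,
    sclin_cm = equivalent_square(A, B))
}
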