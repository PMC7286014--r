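#' Run the full analysis pipeline on a scenario directory
#'
#' Reads the scan files, readings CSV and correction-factor table emitted
#' under `dir` (by [generate_scenario()] or by compatible measurement
#' exports), measures the equivalent square size of every field from its
#' profile pair, builds per-detector output factor tables, and summarises
#' the cross-detector spread before and after correction.
#'
#' @param dir Directory containing `profiles_*.scan`, `readings.csv` and
#'   `ktable.csv`.
#' @param method `"direct"` or `"ifm"`.
#' @param detectors_in_stats Detector labels pooled in the spread summary
#'   (default `c("CC01", "PFD", "EFD")`); other detectors are still
#'   analysed and reported raw.
#' @param msr_side_cm Reference field side (default 10).
#' @param ifm_int_side_cm Intermediate field side for `method = "ifm"`
#'   (default 4).
#' @param ifm_ic_detector Reference-chamber label for the intermediate leg
#'   (default `"REF"`).
#' @return List: `geometries` (side, widths, measured `S_clin`),
#'   `fof_tables` (named list of `fof_table`), `summary_uncorrected` and
#'   `summary_corrected` (`comparison_report`s).
#' @export
analyze_scenario <- function(dir, method = c("direct", "ifm"),
                             detectors_in_stats = c("CC01", "PFD", "EFD"),
                             msr_side_cm = 10, ifm_int_side_cm = 4,
                             ifm_ic_detector = "REF") {
  method <- match.arg(method)
  prof_files <- sort(list.files(dir, pattern = "^profiles_.*\\.scan$",
                                full.names = TRUE))
  if (!length(prof_files)) {
    stop_sf(sprintf("no profile scan files under %s", dir), "sfdose_io_error")
  }
  geoms <- do.call(rbind, lapply(prof_files, function(p) {
    ss <- read_scan_table(p)
    axes <- vapply(ss$curves, function(cv) cv$axis, "")
    cross <- ss$curves[[match("crossline", axes)]]
    inpl <- ss$curves[[match("inline", axes)]]
    geo <- sclin_from_profiles(cross, inpl)
    data.frame(side_cm = cross$field_x_cm, sclin_cm = geo$sclin_cm,
               fwhm_cross_cm = geo$fwhm_cross_cm,
               fwhm_in_cm = geo$fwhm_in_cm)
  }))
  geoms <- geoms[order(-geoms$side_cm), , drop = FALSE]
  rownames(geoms) <- NULL

  readings <- read_readings(file.path(dir, "readings.csv"))
  ktables <- read_k_table(file.path(dir, "ktable.csv"))

  ifm_config <- NULL
  if (method == "ifm") {
    if (!ifm_ic_detector %in% names(readings)) {
      stop_sf(sprintf("reference chamber '%s' has no readings",
                      ifm_ic_detector), "sfdose_configuration_error")
    }
    ifm_config <- list(int_side_cm = ifm_int_side_cm,
                       ic_readings = readings[[ifm_ic_detector]],
                       ic_k_table = ktables[[ifm_ic_detector]])
  }

  fof_tables <- list()
  for (det in names(readings)) {
    if (is.null(ktables[[det]])) {
      stop_sf(sprintf("no correction factor table for detector '%s'", det),
              "sfdose_configuration_error")
    }
    det_method <- if (method == "ifm" && det == ifm_ic_detector) "direct"
                  else method
    fof_tables[[det]] <- build_fof_table(
      readings[[det]], geoms, ktables[[det]], method = det_method,
      msr_side_cm = msr_side_cm, ifm_config = ifm_config)
  }

  in_stats <- intersect(detectors_in_stats, names(fof_tables))
  list(geometries = geoms,
       fof_tables = fof_tables,
       summary_uncorrected = summarize_fof(fof_tables, in_stats,
                                           value = "fof_uncorrected"),
       summary_corrected = summarize_fof(fof_tables, in_stats,
                                         value = "fof_corrected"))
}
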