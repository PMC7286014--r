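#' Scan curve container
#'
#' A `scan_curve` holds one water-phantom scan: either a depth-dose curve
#' (`axis = "depth"`) or a lateral profile (`axis = "crossline"` or
#' `"inline"`), together with the geometry it was acquired in. Positions are
#' millimetres (depth positive downward from the water surface; lateral
#' coordinates zero at the beam central axis). Values are relative dose in
#' arbitrary or percent units.
#'
#' @param axis One of `"depth"`, `"crossline"`, `"inline"`.
#' @param positions Strictly increasing numeric coordinates in mm.
#' @param values Non-negative relative dose values, same length as
#'   `positions` (at least 5 points).
#' @param detector_id Detector label, e.g. `"CC01"`.
#' @param field_x_cm,field_y_cm Collimator setting (cm) at 100 cm.
#' @param ssd_cm Source-surface distance in cm.
#' @param scan_depth_mm Depth of a lateral profile in mm; must be `NULL` for
#'   depth curves and present for lateral profiles.
#' @param normalized One of `"raw"`, `"max100"` (depth curve scaled to 100 at
#'   its maximum), `"cax100"` (profile scaled to 100 on the central axis).
#'
#' @return An object of class `scan_curve`.
#' @export
scan_curve <- function(axis, positions, values, detector_id = "unknown",
                       field_x_cm = NA_real_, field_y_cm = NA_real_,
                       ssd_cm = 100, scan_depth_mm = NULL,
                       normalized = "raw") {
  axis <- match.arg(axis, c("depth", "crossline", "inline"))
  normalized <- match.arg(normalized, c("raw", "max100", "cax100"))
  positions <- as.numeric(positions)
  values <- as.numeric(values)
  if (length(positions) != length(values)) {
    stop_sf("positions and values must have equal length",
            "sfdose_validation_error")
  }
  if (length(positions) < 5L) {
    stop_sf("a scan curve needs at least 5 points", "sfdose_validation_error")
  }
  if (any(!is.finite(positions)) || any(!is.finite(values))) {
    stop_sf("positions and values must be finite", "sfdose_validation_error")
  }
  if (any(diff(positions) <= 0)) {
    stop_sf("positions must be strictly increasing", "sfdose_validation_error")
  }
  if (any(values < 0)) {
    stop_sf("values must be non-negative", "sfdose_validation_error")
  }
  if (axis == "depth" && !is.null(scan_depth_mm)) {
    stop_sf("scan_depth_mm must be absent for a depth curve",
            "sfdose_validation_error")
  }
  if (axis != "depth" && is.null(scan_depth_mm)) {
    stop_sf("scan_depth_mm is required for a lateral profile",
            "sfdose_validation_error")
  }
  structure(
    list(axis = axis, positions = positions, values = values,
         detector_id = as.character(detector_id),
         field_x_cm = as.numeric(field_x_cm),
         field_y_cm = as.numeric(field_y_cm),
         ssd_cm = as.numeric(ssd_cm),
         scan_depth_mm = if (is.null(scan_depth_mm)) NULL
                         else as.numeric(scan_depth_mm),
         normalized = normalized),
    class = "scan_curve"
  )
}

#' @export
print.scan_curve <- function(x, ...) {
  depth <- if (is.null(x$scan_depth_mm)) "" else
    sprintf(" @ %g mm depth", x$scan_depth_mm)
  cat(sprintf(
    "<scan_curve> %s%s, %s, field %g x %g cm, SSD %g cm, %d pts [%g, %g] mm (%s)\n",
    x$axis, depth, x$detector_id, x$field_x_cm, x$field_y_cm, x$ssd_cm,
    length(x$positions), min(x$positions), max(x$positions), x$normalized))
  invisible(x)
}

curve_key <- function(curve) {
  paste(curve$detector_id, curve$axis, curve$field_x_cm, curve$field_y_cm,
        if (is.null(curve$scan_depth_mm)) "NA" else curve$scan_depth_mm,
        sep = "|")
}

#' Scan set container
#'
#' A collection of [scan_curve()] objects, unique in
#' (detector, axis, field, scan depth), with free-text provenance metadata.
#'
#' @param curves List of `scan_curve` objects.
#' @param provenance Named character vector or list of metadata
#'   (machine, energy, date, ...).
#' @return An object of class `scan_set`.
#' @export
scan_set <- function(curves, provenance = character()) {
  if (!is.list(curves) || !all(vapply(curves, inherits, TRUE, "scan_curve"))) {
    stop_sf("curves must be a list of scan_curve objects",
            "sfdose_validation_error")
  }
  keys <- vapply(curves, curve_key, "")
  if (anyDuplicated(keys)) {
    stop_sf(sprintf("duplicate curve key: %s", keys[duplicated(keys)][1]),
            "sfdose_validation_error")
  }
  structure(list(curves = curves, provenance = provenance),
            class = "scan_set")
}

#' @export
print.scan_set <- function(x, ...) {
  cat(sprintf("<scan_set> %d curve(s)\n", length(x$curves)))
  for (cv in x$curves) print(cv)
  invisible(x)
}

#' @export
length.scan_set <- function(x) length(x$curves)

scan_header_keys <- c("detector", "field_x_cm", "field_y_cm", "ssd_cm",
                      "axis", "depth_mm", "units", "normalized")

#' Read scan curves from a text scan file
#'
#' Parses the plain-text scan dialect: header lines `#key=value` (keys:
#' `detector`, `field_x_cm`, `field_y_cm`, `ssd_cm`, `axis`, `depth_mm` for
#' lateral profiles, optional `units`, `normalized`), followed by
#' comma-separated `position_mm,value` rows. Several curves may share a file,
#' each introduced by a fresh header block. Rows are sorted by position.
#'
#' @param path Path to a scan file.
#' @return A [scan_set()].
#' @export
read_scan_table <- function(path) {
  if (!file.exists(path)) {
    stop_sf(sprintf("scan file not found: %s", path), "sfdose_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  curves <- list()
  meta <- list()
  pos <- numeric()
  val <- numeric()
  in_data <- FALSE

  flush_curve <- function() {
    if (!length(pos)) return(invisible())
    o <- order(pos)
    ax <- meta[["axis"]]
    if (is.null(ax)) {
      stop_sf("scan block is missing the `axis` header", "sfdose_parse_error")
    }
    curves[[length(curves) + 1L]] <<- scan_curve(
      axis = ax, positions = pos[o], values = val[o],
      detector_id = meta[["detector"]] %||% "unknown",
      field_x_cm = as.numeric(meta[["field_x_cm"]] %||% NA),
      field_y_cm = as.numeric(meta[["field_y_cm"]] %||% NA),
      ssd_cm = as.numeric(meta[["ssd_cm"]] %||% 100),
      scan_depth_mm = if (ax == "depth" || is.null(meta[["depth_mm"]])) NULL
                      else as.numeric(meta[["depth_mm"]]),
      normalized = meta[["normalized"]] %||% "raw")
    pos <<- numeric(); val <<- numeric()
  }

  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    if (startsWith(line, "#")) {
      if (in_data) {            # new header block => new curve
        flush_curve()
        meta <- list()
        in_data <- FALSE
      }
      kv <- sub("^#", "", line)
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq < 0) {
        stop_sf(sprintf("line %d: header without '=': %s", i, line),
                "sfdose_parse_error")
      }
      key <- trimws(substr(kv, 1L, eq - 1L))
      if (!key %in% scan_header_keys) {
        stop_sf(sprintf("line %d: unknown header key '%s'", i, key),
                "sfdose_parse_error")
      }
      meta[[key]] <- trimws(substr(kv, eq + 1L, nchar(kv)))
    } else {
      parts <- strsplit(line, ",", fixed = TRUE)[[1]]
      if (length(parts) != 2L) {
        stop_sf(sprintf("line %d: expected 'position_mm,value', got: %s",
                        i, line), "sfdose_parse_error")
      }
      xy <- suppressWarnings(as.numeric(parts))
      if (any(is.na(xy))) {
        stop_sf(sprintf("line %d: non-numeric position or value: %s",
                        i, line), "sfdose_parse_error")
      }
      pos <- c(pos, xy[1]); val <- c(val, xy[2])
      in_data <- TRUE
    }
  }
  flush_curve()
  if (!length(curves)) {
    stop_sf(sprintf("no curves found in %s", path), "sfdose_parse_error")
  }
  scan_set(curves)
}

#' Write scan curves to the text scan dialect
#'
#' Inverse of [read_scan_table()]; numeric fields are printed with enough
#' digits that a write-read round trip reproduces the doubles exactly.
#'
#' @param x A [scan_set()] or single [scan_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(x, path) {
  if (inherits(x, "scan_curve")) x <- scan_set(list(x))
  if (!inherits(x, "scan_set")) {
    stop_sf("x must be a scan_set or scan_curve", "sfdose_argument_error")
  }
  out <- character()
  for (cv in x$curves) {
    out <- c(out,
      sprintf("#detector=%s", cv$detector_id),
      sprintf("#axis=%s", cv$axis),
      sprintf("#field_x_cm=%s", fmt_num(cv$field_x_cm)),
      sprintf("#field_y_cm=%s", fmt_num(cv$field_y_cm)),
      sprintf("#ssd_cm=%s", fmt_num(cv$ssd_cm)),
      if (!is.null(cv$scan_depth_mm))
        sprintf("#depth_mm=%s", fmt_num(cv$scan_depth_mm)),
      sprintf("#normalized=%s", cv$normalized),
      sprintf("%s,%s", fmt_num(cv$positions), fmt_num(cv$values)))
  }
  writeLines(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
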