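#' @keywords internal
"_PACKAGE"

# Reporting precision used throughout: field widths 0.01 cm, output factors
# 3 decimals, %SD 1 decimal. round() in R is round-half-even, which is the
# convention adopted for all printed reports.
round_width <- function(x) round(x, 2L)
round_fof <- function(x) round(x, 3L)
round_psd <- function(x) round(x, 1L)

stop_sf <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "sfdose_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

warn_sf <- function(msg, class) {
  warning(structure(
    class = c(class, "sfdose_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_sf(sprintf("`%s` must be finite and strictly positive", name),
            "sfdose_argument_error")
  }
  invisible(x)
}

# %.17g formatting guarantees exact double round-trip through as.numeric(),
# which the scenario writer relies on for bit-reproducible files.
fmt_num <- function(x) sprintf("%.17g", x)

#' Path to a bundled example data file
#'
#' @param file File name under `inst/extdata`; `NULL` lists available files.
#' @return Full path, or a character vector of file names.
#' @export
sf_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "sfdose")))
  }
  path <- system.file("extdata", file, package = "sfdose")
  if (!nzchar(path)) {
    stop_sf(sprintf("no example file '%s'", file), "sfdose_io_error")
  }
  path
}
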