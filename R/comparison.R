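#' Sample standard deviation (n - 1 divisor)
#'
#' The divisor convention matters when only three detectors are pooled; the
#' n - 1 (sample) form is used for every summary in this package.
#'
#' @param values Numeric vector, length at least 2.
#' @return `sqrt(sum((x - mean)^2) / (n - 1))`.
#' @export
sample_sd <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || any(!is.finite(values))) {
    stop_sf("at least 2 finite values are required", "sfdose_argument_error")
  }
  stats::sd(values)
}

#' Percent standard deviation
#'
#' Sample SD divided by the mean, times 100: the dimensionless spread used
#' to compare detectors and commissioning datasets.
#'
#' @param values Numeric vector, length at least 2, positive mean.
#' @return %SD (percent).
#' @export
percent_sd <- function(values) {
  s <- sample_sd(values)
  m <- mean(values)
  if (m <= 0) {
    stop_sf("percent SD needs a positive mean", "sfdose_argument_error")
  }
  s / m * 100
}

new_comparison_report <- function(df, kind) {
  stopifnot(is.data.frame(df))
  attr(df, "kind") <- kind
  class(df) <- c("comparison_report", class(df))
  df
}

#' Cross-detector summary of output factor tables
#'
#' Pools the chosen detectors per field size into mean, sample SD and %SD;
#' detectors outside `detectors_in_stats` are carried along as raw columns
#' but excluded from the statistics (the convention used when reference-
#' class detectors are shown alongside the small-field set).
#'
#' @param tables Either a named list of `fof_table` objects (names are
#'   detector ids) or a wide data frame whose first column is the field-size
#'   index and remaining columns are per-detector values.
#' @param detectors_in_stats Character vector of detector labels to pool.
#'   Defaults to all detectors.
#' @param value For a list of `fof_table`s, which column to summarise
#'   (default `"fof_corrected"`).
#' @return A `comparison_report` data frame: index column, per-detector
#'   values, `mean`, `sd`, `percent_sd`.
#' @export
summarize_fof <- function(tables, detectors_in_stats = NULL,
                          value = "fof_corrected") {
  wide <- if (is.data.frame(tables)) tables else fof_wide(tables, value)
  idx_name <- names(wide)[1L]
  dets <- names(wide)[-1L]
  if (is.null(detectors_in_stats)) detectors_in_stats <- dets
  missing <- setdiff(detectors_in_stats, dets)
  if (length(missing)) {
    stop_sf(sprintf("detectors not present: %s",
                    paste(missing, collapse = ", ")),
            "sfdose_consistency_error")
  }
  if (length(detectors_in_stats) < 2L) {
    stop_sf("at least 2 detectors are needed for a spread statistic",
            "sfdose_argument_error")
  }
  pool <- as.matrix(wide[, detectors_in_stats, drop = FALSE])
  if (any(is.na(pool))) {
    stop_sf("pooled detectors have missing values at some field sizes",
            "sfdose_consistency_error")
  }
  out <- wide
  out$mean <- apply(pool, 1L, mean)
  out$sd <- apply(pool, 1L, sample_sd)
  out$percent_sd <- out$sd / out$mean * 100
  attr(out, "detectors_in_stats") <- detectors_in_stats
  new_comparison_report(out, kind = "fof")
}

#' Spread output factor tables into a wide detector matrix
#'
#' @param tables Named list of `fof_table` objects.
#' @param value Column to extract (e.g. `"fof_uncorrected"`,
#'   `"fof_corrected"`).
#' @return Data frame: `collimator_side_cm` plus one column per detector.
#' @export
fof_wide <- function(tables, value = "fof_corrected") {
  stopifnot(is.list(tables), length(tables) >= 1L)
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- vapply(tables, function(t) attr(t, "detector_id"), "")
  }
  idx <- tables[[1L]]$collimator_side_cm
  for (t in tables) {
    if (!isTRUE(all.equal(t$collimator_side_cm, idx))) {
      stop_sf("output factor tables do not share a field-size index",
              "sfdose_consistency_error")
    }
  }
  out <- data.frame(collimator_side_cm = idx)
  for (nm in names(tables)) out[[nm]] <- tables[[nm]][[value]]
  out
}

#' MLC-defined vs jaw-defined output factor ratios
#'
#' Per field size, the ratio of the MLC-defined to the jaw-defined output
#' factor of the same detector (MLC fields with a fixed jaw offset read
#' slightly high, increasingly so at small sizes).
#'
#' @param fof_mlc,fof_jaw `fof_table` objects or data frames with columns
#'   `collimator_side_cm` and a value column.
#' @param value Value column name (default `"fof_uncorrected"`).
#' @return Data frame: `collimator_side_cm`, `mlc`, `jaw`, `ratio`,
#'   `ratio_printed` (3 decimals).
#' @export
mlc_jaw_ratios <- function(fof_mlc, fof_jaw, value = "fof_uncorrected") {
  get_cols <- function(df) {
    stopifnot(is.data.frame(df))
    v <- if (value %in% names(df)) df[[value]] else df[[2L]]
    data.frame(side = df$collimator_side_cm, v = v)
  }
  a <- get_cols(fof_mlc); b <- get_cols(fof_jaw)
  if (!isTRUE(all.equal(a$side, b$side))) {
    stop_sf("MLC and jaw tables do not share a field-size index",
            "sfdose_consistency_error")
  }
  check_positive(b$v, "jaw output factors")
  data.frame(collimator_side_cm = a$side, mlc = a$v, jaw = b$v,
             ratio = a$v / b$v, ratio_printed = round_fof(a$v / b$v))
}

#' Read a monitor-unit comparison CSV
#'
#' Columns: `case,technique,dataset_label,mu`; one row per (case, dataset).
#'
#' @param path CSV file path.
#' @return Data frame with those columns, techniques validated against
#'   `symmetric`, `imrt`, `vmat`.
#' @export
read_mu_table <- function(path) {
  if (!file.exists(path)) {
    stop_sf(sprintf("MU file not found: %s", path), "sfdose_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case", "technique", "dataset_label", "mu")
  if (!all(need %in% names(df))) {
    stop_sf(sprintf("MU file must have columns %s",
                    paste(need, collapse = ", ")), "sfdose_parse_error")
  }
  bad <- setdiff(unique(df$technique), c("symmetric", "imrt", "vmat"))
  if (length(bad)) {
    stop_sf(sprintf("unknown technique(s): %s", paste(bad, collapse = ", ")),
            "sfdose_parse_error")
  }
  if (any(df$mu <= 0)) stop_sf("MU must be positive", "sfdose_validation_error")
  df
}

#' Per-case %SD of calculated monitor units across commissioning datasets
#'
#' For each case, the mean, sample SD and %SD of the MU values calculated
#' under each commissioning dataset (the spread that shrinks when corrected
#' output factors are commissioned).
#'
#' @param cases Data frame as returned by [read_mu_table()].
#' @return A `comparison_report` data frame: `case`, `technique`, `n`,
#'   `mean_mu`, `sd_mu`, `percent_sd`.
#' @export
mu_percent_sd <- function(cases) {
  stopifnot(is.data.frame(cases),
            all(c("case", "technique", "mu") %in% names(cases)))
  keys <- unique(cases[, c("case", "technique")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- cases[cases$case == keys$case[i] &
                 cases$technique == keys$technique[i], , drop = FALSE]
    if (nrow(sub) < 2L) {
      stop_sf(sprintf("case %s needs at least 2 datasets", keys$case[i]),
              "sfdose_argument_error")
    }
    data.frame(case = keys$case[i], technique = keys$technique[i],
               n = nrow(sub), mean_mu = mean(sub$mu),
               sd_mu = sample_sd(sub$mu), percent_sd = percent_sd(sub$mu))
  })
  new_comparison_report(do.call(rbind, rows), kind = "mu")
}

#' %SD from a printed (mean, SD) summary
#'
#' Recovers the percent standard deviation from an already-summarised
#' mean and SD pair, e.g. the labels printed beside commissioning plots.
#'
#' @param mean_value,sd_value Summary mean (> 0) and SD (>= 0).
#' @return `sd_value / mean_value * 100`.
#' @export
percent_sd_from_summary <- function(mean_value, sd_value) {
  check_positive(mean_value, "mean_value")
  if (any(sd_value < 0)) {
    stop_sf("sd_value must be non-negative", "sfdose_argument_error")
  }
  sd_value / mean_value * 100
}

#' Serialise a comparison report
#'
#' Deterministic serialisation with report rounding applied (output factors
#' 3 decimals, %SD 1 decimal, widths 0.01 cm); re-reading a CSV or JSON
#' report reproduces the rounded values.
#'
#' @param report A `comparison_report` (or plain data frame).
#' @param path Output file path.
#' @param format `"csv"`, `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
render_report <- function(report, path, format = c("csv", "json", "markdown")) {
  format <- match.arg(format)
  if (!is.data.frame(report) || !nrow(report)) {
    stop_sf("report must be a non-empty data frame", "sfdose_argument_error")
  }
  df <- as.data.frame(report)
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]])) next
    df[[nm]] <- if (nm %in% c("percent_sd")) round_psd(df[[nm]])
                else if (nm %in% c("collimator_side_cm", "case", "n")) df[[nm]]
                else if (grepl("_cm$", nm)) round_width(df[[nm]])
                else round_fof(df[[nm]])
  }
  ok <- tryCatch({
    switch(format,
      csv = utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
      json = jsonlite::write_json(df, path, digits = NA, dataframe = "rows"),
      markdown = writeLines(markdown_table(df), path))
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) {
    stop_sf(sprintf("could not write report to %s", path), "sfdose_io_error")
  }
  invisible(path)
}

markdown_table <- function(df) {
  cells <- vapply(df, function(col) format(col, trim = TRUE),
                  character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L,
                                      dimnames = list(NULL, names(df)))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("|", paste(rep(" --- ", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, rule, body)
}
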