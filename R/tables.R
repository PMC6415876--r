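#' Paired measurement tables
#'
#' A `measurement_table` is a data frame of paired percentage measurements of
#' the same samples by two methods: the device under evaluation and the
#' reference (manual) method. Both values live on the 0--100 scale.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param device numeric vector of device measurements (0--100).
#' @param reference numeric vector of reference measurements (0--100).
#' @return data frame of class `measurement_table` with columns
#'   `sample_id`, `device`, `reference`.
#' @export
measurement_table <- function(sample_id, device, reference) {
  sample_id <- as.character(sample_id)
  device <- as.numeric(device)
  reference <- as.numeric(reference)
  n <- length(sample_id)
  if (n < 2L)
    stop_spermfx("a measurement table needs at least 2 rows", "empty_input_error")
  if (length(device) != n || length(reference) != n)
    stop_spermfx("columns must have equal length", "shape_error")
  if (anyDuplicated(sample_id))
    stop_spermfx("duplicate sample_id values", "schema_error")
  if (any(!is.finite(device)) || any(!is.finite(reference)))
    stop_spermfx("non-finite measurement values", "parameter_error")
  if (any(device < 0 | device > 100) || any(reference < 0 | reference > 100))
    stop_spermfx("measurements must lie in [0, 100]", "parameter_error")
  structure(
    data.frame(sample_id = sample_id, device = device, reference = reference,
               stringsAsFactors = FALSE),
    class = c("measurement_table", "data.frame")
  )
}

#' Load a paired-measurement table from CSV or XLSX
#'
#' Reads a table of paired (device, reference) percentage measurements.
#' CSV files must carry a header row; for XLSX workbooks the sheets are
#' scanned and the first sheet containing both named columns is used.
#' Rows with a missing value in either column are dropped; the number of
#' dropped rows is recorded in the `n_dropped` attribute.
#'
#' @param path CSV or XLSX file.
#' @param device_col,reference_col column names holding the device and
#'   reference measurements.
#' @param sample_col optional column with sample identifiers; row numbers
#'   are used when absent.
#' @return A [measurement_table()] with attribute `n_dropped`.
#' @export
read_measurement_table <- function(path, device_col, reference_col,
                                   sample_col = NULL) {
  if (!file.exists(path))
    stop_spermfx(paste0("no such file: ", path), "io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    sheets <- readxl::excel_sheets(path)
    df <- NULL
    for (s in sheets) {
      cand <- as.data.frame(readxl::read_excel(path, sheet = s))
      if (all(c(device_col, reference_col) %in% names(cand))) { df <- cand; break }
    }
    if (is.null(df))
      stop_spermfx(sprintf("no sheet contains columns '%s' and '%s'",
                           device_col, reference_col), "schema_error")
  } else {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  for (cl in c(device_col, reference_col))
    if (!cl %in% names(df))
      stop_spermfx(paste0("missing column: ", cl), "schema_error")
  dv <- suppressWarnings(as.numeric(df[[device_col]]))
  rf <- suppressWarnings(as.numeric(df[[reference_col]]))
  keep <- is.finite(dv) & is.finite(rf)
  n_dropped <- sum(!keep)
  if (!any(keep))
    stop_spermfx("no usable rows after dropping missing values", "empty_input_error")
  ids <- if (!is.null(sample_col) && sample_col %in% names(df))
    as.character(df[[sample_col]]) else sprintf("row%03d", seq_len(nrow(df)))
  tab <- measurement_table(ids[keep], dv[keep], rf[keep])
  attr(tab, "n_dropped") <- n_dropped
  tab
}
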