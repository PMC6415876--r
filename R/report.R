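#' Analysis reports
#'
#' Shared result container for all assays. A report records which assay was
#' run, the parameters used (echoed verbatim), the numeric results, and
#' provenance (input identifiers plus a digest of the configuration).
#'
#' @param assay one of `"hba"`, `"dna_frag"`, `"viability"`, `"comparison"`.
#' @param parameters named list of the configuration used.
#' @param results named list of numeric/character results.
#' @param inputs character vector identifying the inputs.
#' @return object of class `analysis_report`.
#' @export
analysis_report <- function(assay, parameters = list(), results = list(),
                            inputs = character()) {
  assay <- match.arg(assay, c("hba", "dna_frag", "viability", "comparison"))
  pct <- grepl("percent|score$|viable|sensitivity|specificity|accuracy",
               names(results))
  for (i in which(pct)) {
    v <- results[[i]]
    if (is.numeric(v) && length(v) == 1L && is.finite(v) && (v < 0 || v > 100))
      stop_spermfx(sprintf("reported percentage '%s' outside [0, 100]",
                           names(results)[i]), "parameter_error")
  }
  serialized <- paste(names(parameters),
                      vapply(parameters, function(p) paste(format(p), collapse = ","),
                             character(1)),
                      sep = "=", collapse = ";")
  bytes <- if (nzchar(serialized)) utf8ToInt(serialized) else 0L
  digest <- sprintf("%08x", sum(bytes * seq_along(bytes)) %% 0xFFFFFFF)
  structure(list(assay = assay, parameters = parameters, results = results,
                 provenance = list(inputs = inputs, config_digest = digest)),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report: %s>\n", x$assay))
  for (nm in names(x$results)) {
    v <- x$results[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (is.numeric(v)) paste(format(round(v, 2)), collapse = ", ")
                else paste(v, collapse = ", ")))
  }
  invisible(x)
}

#' Write an analysis report to JSON or CSV
#'
#' JSON is the canonical format and round-trips all numeric fields at full
#' double precision; CSV is a flat `section,key,value` table with values
#' printed at 17 significant digits (lossless for doubles).
#'
#' @param report an [analysis_report()].
#' @param path output file; the parent directory must exist.
#' @param format `"json"` or `"csv"` (default from the file extension).
#' @export
write_report <- function(report, path, format = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(dirname(path)))
    stop_spermfx("parent directory does not exist", "io_error")
  format <- format %||% (if (tolower(tools::file_ext(path)) == "csv") "csv" else "json")
  format <- match.arg(format, c("json", "csv"))
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    flat <- function(section, lst) {
      if (length(lst) == 0L) return(NULL)
      data.frame(section = section, key = names(lst),
                 value = vapply(lst, function(v)
                   paste(format(v, digits = 17), collapse = "|"), character(1)),
                 stringsAsFactors = FALSE)
    }
    out <- rbind(flat("meta", list(assay = report$assay)),
                 flat("parameters", report$parameters),
                 flat("results", report$results),
                 flat("provenance", report$provenance))
    write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back an analysis report written by [write_report()]
#'
#' @param path JSON or CSV report file.
#' @return an [analysis_report()] (JSON) or the flat data frame (CSV).
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_spermfx(paste0("no such file: ", path), "io_error")
  if (tolower(tools::file_ext(path)) == "csv")
    return(read.csv(path, stringsAsFactors = FALSE))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "analysis_report")
}
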