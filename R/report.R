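# Conversion-report plumbing. During a conversion, events are collected in a
# mutable environment (cheap appends at genome-map scale) and frozen into a
# ConversionReport at the end.

newReporter <- function() {
  e <- new.env(parent = emptyenv())
  e$severity <- character()
  e$rule <- character()
  e$element <- character()
  e$message <- character()
  e
}

note <- function(rep, severity, rule, element, message) {
  n <- length(rep$severity) + 1L
  rep$severity[n] <- severity
  rep$rule[n] <- rule
  rep$element[n] <- if (is.null(element) || is.na(element)) NA_character_ else element
  rep$message[n] <- message
  invisible(NULL)
}

freezeReport <- function(rep) {
  new("ConversionReport",
      records = data.frame(severity = rep$severity, rule = rep$rule,
                           element = rep$element, message = rep$message,
                           stringsAsFactors = FALSE))
}

#' Build a conversion report
#'
#' Mostly internal — conversions construct their own reports — but exposed so
#' tests and scripts can build or combine reports.
#'
#' @param records data.frame with columns \code{severity}, \code{rule},
#'   \code{element}, \code{message}.
#' @return a [ConversionReport].
#' @export
conversionReport <- function(records = data.frame(
    severity = character(), rule = character(), element = character(),
    message = character(), stringsAsFactors = FALSE)) {
  new("ConversionReport", records = records)
}

#' @rdname conversionReport
#' @param ... reports to concatenate.
#' @export
combineReports <- function(...) {
  recs <- lapply(list(...), reportRecords)
  conversionReport(do.call(rbind, c(recs, list(make.row.names = FALSE))))
}

#' Count report rows by severity
#'
#' @param x a [ConversionReport].
#' @param severity one of \code{"notification"}, \code{"warning"},
#'   \code{"error"}.
#' @return integer count.
#' @export
reportCount <- function(x, severity) {
  sum(reportRecords(x)$severity == severity)
}

#' Write a report as JSON lines
#'
#' One JSON object per record, the schema used by the command-line
#' \code{--report} flag.
#'
#' @param x a [ConversionReport].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeReportJson <- function(x, path) {
  r <- reportRecords(x)
  lines <- vapply(seq_len(nrow(r)), function(i) {
    jsonlite::toJSON(as.list(r[i, , drop = FALSE]), auto_unbox = TRUE,
                     na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
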