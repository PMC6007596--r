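#' Write and read timed event tables
#'
#' Event tables (columns `replicate`, `family`, `type`, `branch`, `time`) are
#' written as TSV or JSON at full double precision so that a write-then-read
#' cycle reproduces the event set exactly.
#'
#' @param events a data frame of events, or a [dollo_map] (its `$events` is
#'   used).
#' @param path output file path; a `.json` extension selects JSON, anything
#'   else TSV, unless `format` is given.
#' @param format `"tsv"` or `"json"`; default inferred from `path`.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, format = NULL) {
  if (inherits(events, "dollo_map")) events <- events$events
  stopifnot(all(c("replicate", "family", "type", "branch", "time") %in%
                  names(events)))
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "json") {
    jsonlite::write_json(events, path, dataframe = "columns", digits = NA)
  } else {
    out <- events
    out$time <- sprintf("%.17g", out$time)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  ev <- if (format == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  ev$replicate <- as.integer(ev$replicate)
  ev$branch <- as.integer(ev$branch)
  ev$time <- as.double(ev$time)
  ev
}
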