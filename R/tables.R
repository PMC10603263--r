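# Long-format analysis tables and their CSV export (the 3DViewer-style
# input contract: one file per analysis, stable headers).

#' Create a metric table
#'
#' A data frame tagged with its analysis name; the payload written by
#' [export_tables()].
#'
#' @param analysis_name short stable name (used as the file stem).
#' @param data a data frame.
#' @return A `metric_table` (data frame subclass).
#' @export
metric_table <- function(analysis_name, data) {
  stopifnot(is.character(analysis_name), length(analysis_name) == 1L,
            nzchar(analysis_name), is.data.frame(data))
  structure(data, analysis = analysis_name,
            class = c("metric_table", class(data)))
}

#' @export
print.metric_table <- function(x, ...) {
  cat("metric table ", sQuote(attr(x, "analysis")), ": ", nrow(x),
      " rows\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Export analysis tables
#'
#' Writes one CSV file per table (named `<analysis>.csv`) plus a
#' `manifest.json` listing the files, row counts and column schemas.
#' Floating-point values are serialized with `digits` significant digits,
#' so re-reading reproduces values within that precision.
#'
#' @param tables list of [metric_table()] objects (or plain data frames,
#'   which must be named list entries).
#' @param directory output directory (created if needed).
#' @param format `"csv"`; `"xlsx"` is part of the table contract but no
#'   XLSX writer is available to this package, so it raises an error
#'   directing the user to CSV.
#' @param digits significant digits for numeric serialization.
#' @return Invisibly, the manifest list.
#' @export
export_tables <- function(tables, directory, format = c("csv", "xlsx"),
                          digits = 6) {
  format <- match.arg(format)
  if (format == "xlsx") {
    stop("XLSX export is not supported by this build; use format = \"csv\" ",
         "(the viewer contract accepts either)")
  }
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory)) stop("cannot create directory: ", directory)
  }
  if (file.access(directory, 2) != 0) stop("directory not writable: ", directory)
  manifest <- list(format = format, digits = digits, files = list())
  for (i in seq_along(tables)) {
    tb <- tables[[i]]
    nm <- attr(tb, "analysis")
    if (is.null(nm)) nm <- names(tables)[i]
    if (is.null(nm) || !nzchar(nm)) stop("table ", i, " has no analysis name")
    df <- as.data.frame(tb)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) signif(v, digits))
    path <- file.path(directory, paste0(nm, ".csv"))
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    manifest$files[[nm]] <- list(file = basename(path), rows = nrow(df),
                                 columns = names(df))
  }
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
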