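#' Read a multichannel AA matrix from delimited text
#'
#' Reads a CSV/TSV file with one row per lead and one column per sample. If
#' the first column is non-numeric it is taken as lead labels; an optional
#' header row is detected and skipped. The delimiter is auto-detected by
#' [data.table::fread()].
#'
#' @param path file path.
#' @param fs sampling rate in Hz (not stored in delimited files, so it must
#'   be supplied).
#' @param header whether the file has a header row (default auto-detect).
#'
#' @return An [AASignalSet-class].
#' @export
readAASignals <- function(path, fs, header = "auto") {
    dt <- data.table::fread(path, header = header)
    leadIds <- NULL
    if (ncol(dt) > 1L && !is.numeric(dt[[1L]])) {
        leadIds <- as.character(dt[[1L]])
        dt <- dt[, -1L]
    }
    m <- as.matrix(dt)
    dimnames(m) <- NULL
    AASignalSet(m, fs = fs, leadIds = leadIds)
}

#' Write a multichannel AA matrix to delimited text
#'
#' Writes leads x samples values as CSV with the lead labels in the first
#' column and no header, the format read back by [readAASignals()].
#'
#' @param x an [AASignalSet-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeAASignals <- function(x, path) {
    dt <- data.table::data.table(lead = leadIds(x), aaData(x))
    data.table::fwrite(dt, path, col.names = FALSE)
    invisible(path)
}

#' Write recurrence indices to CSV or JSON
#'
#' @param indices a [RecurrenceIndices-class] or the per-subject data.frame
#'   from [indicesToDataFrame()].
#' @param path output path; format chosen by extension (`.json` for JSON,
#'   otherwise CSV).
#' @param subject optional subject label.
#' @return The path, invisibly.
#' @export
writeIndices <- function(indices, path, subject = NULL) {
    df <- if (is(indices, "RecurrenceIndices"))
        indicesToDataFrame(indices, subject = subject) else indices
    if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                             dataframe = "rows")
    else
        data.table::fwrite(df, path)
    invisible(path)
}
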