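#' Construct an AASignalSet
#'
#' Wrap a leads-by-samples numeric matrix of atrial-activity signals together
#' with its sampling rate and lead labels.
#'
#' @param data numeric matrix, one row per lead, one column per time sample.
#' @param fs sampling rate in Hz.
#' @param leadIds optional character vector of lead labels; defaults to
#'   existing row names or `"L1" .. "Lk"`.
#'
#' @return An [AASignalSet-class] object.
#'
#' @examples
#' x <- AASignalSet(matrix(rnorm(4 * 256), 4), fs = 256)
#' nLeads(x)
#' nSamples(x)
#' @export
AASignalSet <- function(data, fs, leadIds = NULL) {
    data <- as.matrix(data)
    storage.mode(data) <- "double"
    if (is.null(leadIds))
        leadIds <- if (!is.null(rownames(data))) rownames(data)
                   else paste0("L", seq_len(nrow(data)))
    rownames(data) <- leadIds
    new("AASignalSet", data = data, fs = as.numeric(fs),
        leadIds = as.character(leadIds))
}

#' Accessors for AASignalSet
#'
#' `aaData` returns the leads x samples matrix, `samplingRate` the sampling
#' rate in Hz, `leadIds` the lead labels, `nLeads` and `nSamples` the matrix
#' dimensions.
#'
#' @param object an [AASignalSet-class].
#' @return The corresponding slot or dimension.
#' @name AASignalSet-accessors
#' @aliases aaData samplingRate leadIds nLeads nSamples
NULL

#' @rdname AASignalSet-accessors
#' @export
setMethod("aaData", "AASignalSet", function(object) object@data)

#' @rdname AASignalSet-accessors
#' @export
setMethod("samplingRate", "AASignalSet", function(object) object@fs)

#' @rdname AASignalSet-accessors
#' @export
setMethod("leadIds", "AASignalSet", function(object) object@leadIds)

#' @rdname AASignalSet-accessors
#' @export
setMethod("nLeads", "AASignalSet", function(object) nrow(object@data))

#' @rdname AASignalSet-accessors
#' @export
setMethod("nSamples", "AASignalSet", function(object) ncol(object@data))

#' Subset an AASignalSet by leads and samples
#'
#' @param x an [AASignalSet-class].
#' @param i lead index (integer, logical or lead label).
#' @param j sample index.
#' @param ... ignored.
#' @param drop ignored; the result is always an AASignalSet.
#' @return An [AASignalSet-class] with the selected leads/samples.
#' @export
setMethod("[", "AASignalSet", function(x, i, j, ..., drop = FALSE) {
    d <- x@data
    if (missing(i)) i <- seq_len(nrow(d))
    if (missing(j)) j <- seq_len(ncol(d))
    AASignalSet(d[i, j, drop = FALSE], fs = x@fs,
                leadIds = x@leadIds[if (is.character(i))
                    match(i, x@leadIds) else i])
})

setMethod("show", "AASignalSet", function(object) {
    cat("AASignalSet:", nrow(object@data), "leads x", ncol(object@data),
        "samples @", object@fs, "Hz (",
        sprintf("%.1f", ncol(object@data) / object@fs), "s )\n")
    ids <- object@leadIds
    cat("  leads:", paste(head(ids, 4L), collapse = ", "),
        if (length(ids) > 4L) sprintf("... (%d total)", length(ids)) else "",
        "\n")
})

setMethod("show", "RecurrenceSignal", function(object) {
    cat("RecurrenceSignal: block", object@blockIndex, "-", length(object@r),
        "lags; r(0) =", format(object@r[1L]), "\n")
})

setMethod("show", "RecurrenceIndices", function(object) {
    cat("RecurrenceIndices over", object@nBlocks, "blocks (",
        object@nDegenerate, "degenerate )\n")
    cat(sprintf("  LTR   = %.4f\n", object@ltr))
    cat(sprintf("  |P1|  = %.4f at t_P1 = %.1f samples\n",
                object@absP1, object@tP1))
    cat(sprintf("  P2    = %.4f at t_P2 = %.1f samples\n",
                object@p2, object@tP2))
    cat(sprintf("  |P1|/LTR = %.3f, P2/LTR = %.3f\n",
                object@normP1, object@normP2))
})

setMethod("show", "SvaapResult", function(object) {
    cat("SvaapResult:\n")
    cat(sprintf("  s-SVAAP = %.3f over %d segments of q = %d samples\n",
                object@sSvaap, length(object@perSegmentShort), object@q))
    cat(sprintf("  l-SVAAP = %.3f over %d long segments\n",
                object@lSvaap, length(object@perSegmentLong)))
})

setMethod("show", "ModelParams", function(object) {
    cat(sprintf(paste0("ModelParams: d = %g, v = %g, fAF = %g Hz, ",
                       "fs = %g Hz\n"), object@d, object@v, object@fAF,
                object@fs))
    cat(sprintf("  %d intrinsic channels -> %d leads, %d samples (%.1f s)%s\n",
                object@intrinsicDim, object@nLeads, object@nSamples,
                object@nSamples / object@fs,
                if (object@sharedWalk) ", shared walk" else ""))
})

setMethod("show", "FitResult", function(object) {
    cat(sprintf("FitResult: d = %g, v = %g (f_AF offset %+g Hz), score = %.5f\n",
                object@bestD, object@bestV, object@bestOffset,
                min(object@scoreSurface, na.rm = TRUE)))
})

setMethod("show", "SpectralEstimate", function(object) {
    cat(sprintf("SpectralEstimate: f_AF = %.2f Hz (band %g-%g Hz, %d leads)%s%s\n",
                object@fAF, object@band[1L], object@band[2L],
                length(object@perLeadF),
                if (object@edgeFlag) " [band-limited]" else "",
                if (!object@reliable) " [unreliable peak]" else ""))
})
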