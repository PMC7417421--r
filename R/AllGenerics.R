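#' @rdname AASignalSet-accessors
#' @export
setGeneric("aaData", function(object) standardGeneric("aaData"))

#' @rdname AASignalSet-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname AASignalSet-accessors
#' @export
setGeneric("leadIds", function(object) standardGeneric("leadIds"))

#' @rdname AASignalSet-accessors
#' @export
setGeneric("nLeads", function(object) standardGeneric("nLeads"))

#' @rdname AASignalSet-accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname recurrenceSignal
#' @export
setGeneric("recurrenceSignal", function(object, ...)
    standardGeneric("recurrenceSignal"))

#' @rdname subjectIndices
#' @export
setGeneric("subjectIndices", function(object, ...)
    standardGeneric("subjectIndices"))

#' @rdname kneeDimension
#' @export
setGeneric("kneeDimension", function(object, ...)
    standardGeneric("kneeDimension"))
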