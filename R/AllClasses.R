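#' Multichannel atrial-activity signal set
#'
#' Container for a multichannel atrial-activity (AA) recording: a numeric
#' matrix with one row per lead and one column per time sample, together with
#' the sampling rate and lead labels. Each column is interpreted as the
#' instantaneous spatial AA vector seen by all electrodes.
#'
#' @slot data numeric matrix, leads x samples.
#' @slot fs sampling rate in Hz.
#' @slot leadIds character vector of lead labels, one per row.
#'
#' @seealso [AASignalSet()] for the constructor, [subjectIndices()],
#'   [svaap()].
#' @name AASignalSet-class
#' @aliases AASignalSet-class
#' @exportClass AASignalSet
setClass("AASignalSet",
    slots = c(data = "matrix", fs = "numeric", leadIds = "character"))

setValidity("AASignalSet", function(object) {
    msg <- NULL
    d <- object@data
    if (!is.numeric(d))
        msg <- c(msg, "'data' must be a numeric matrix")
    else {
        if (nrow(d) < 2L)
            msg <- c(msg, "at least 2 leads are required")
        if (ncol(d) < 1L)
            msg <- c(msg, "at least 1 sample is required")
        if (anyNA(d) || any(!is.finite(d)))
            msg <- c(msg, "'data' must not contain non-finite entries")
    }
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
        msg <- c(msg, "'fs' must be a single positive number")
    if (length(object@leadIds) != nrow(d))
        msg <- c(msg, "'leadIds' must have one entry per lead")
    if (is.null(msg)) TRUE else msg
})

#' Block-wise recurrence matrix
#'
#' Square matrix of cosine similarities between spatial AA vectors within one
#' analysis block. Entry (i, j) is the cosine of the angle between the spatial
#' vectors at time i and time i + j - 1, so column j collects similarities at
#' lag p = j - 1. The first column is identically 1.
#'
#' @slot values numeric M x M matrix with entries in [-1, 1].
#' @slot blockIndex 1-based index of the block within the recording.
#'
#' @seealso [recurrenceMatrix()], [recurrenceSignal()]
#' @name RecurrenceMatrix-class
#' @exportClass RecurrenceMatrix
setClass("RecurrenceMatrix",
    slots = c(values = "matrix", blockIndex = "integer"))

setValidity("RecurrenceMatrix", function(object) {
    v <- object@values
    tol <- 1e-9
    msg <- NULL
    if (nrow(v) != ncol(v))
        msg <- c(msg, "'values' must be square")
    if (any(abs(v) > 1 + tol))
        msg <- c(msg, "entries must lie in [-1, 1]")
    if (any(abs(v[, 1L] - 1) > tol))
        msg <- c(msg, "first column must be identically 1")
    if (length(object@blockIndex) != 1L || object@blockIndex < 1L)
        msg <- c(msg, "'blockIndex' must be a single positive integer")
    if (is.null(msg)) TRUE else msg
})

#' Multi-variable AA recurrence signal
#'
#' Lag-indexed mean cosine similarity of spatial AA vectors within one block:
#' r(p) is the column mean of the block's recurrence matrix at lag
#' p = 0, ..., M - 1. By construction r(0) = 1 and |r(p)| <= 1.
#'
#' @slot r numeric vector of length M; element p + 1 holds lag p.
#' @slot blockIndex 1-based block index.
#'
#' @seealso [recurrenceSignal()], [shortTermPeaks()], [ltrFromBlocks()]
#' @name RecurrenceSignal-class
#' @exportClass RecurrenceSignal
setClass("RecurrenceSignal",
    slots = c(r = "numeric", blockIndex = "integer"))

setValidity("RecurrenceSignal", function(object) {
    tol <- 1e-9
    msg <- NULL
    if (length(object@r) < 1L)
        msg <- c(msg, "'r' must be non-empty")
    else {
        if (abs(object@r[1L] - 1) > tol)
            msg <- c(msg, "r(0) must equal 1")
        if (any(abs(object@r) > 1 + tol))
            msg <- c(msg, "|r(p)| must not exceed 1")
    }
    if (is.null(msg)) TRUE else msg
})

#' Subject-level recurrence indices
#'
#' Characteristic indices of the block-wise recurrence signals of one subject:
#' long-term recurrence (LTR, mean |r(p)| over a fixed lag band averaged over
#' blocks), the absolute first negative peak |P1| and first positive peak P2
#' with their lags t_P1 and t_P2 (averaged over non-degenerate blocks), and
#' the LTR-normalised peaks.
#'
#' @slot ltr long-term recurrence, in [0, 1].
#' @slot absP1 mean absolute first negative peak.
#' @slot p2 mean first positive peak.
#' @slot tP1,tP2 mean lags (samples) of the two peaks.
#' @slot normP1,normP2 absP1 / ltr and p2 / ltr (NA when ltr is 0).
#' @slot nBlocks number of blocks analysed.
#' @slot nDegenerate number of blocks without qualifying peaks (excluded from
#'   the peak averages but retained for LTR).
#'
#' @seealso [subjectIndices()]
#' @name RecurrenceIndices-class
#' @exportClass RecurrenceIndices
setClass("RecurrenceIndices",
    slots = c(ltr = "numeric", absP1 = "numeric", p2 = "numeric",
              tP1 = "numeric", tP2 = "numeric",
              normP1 = "numeric", normP2 = "numeric",
              nBlocks = "integer", nDegenerate = "integer"))

setValidity("RecurrenceIndices", function(object) {
    msg <- NULL
    tol <- 1e-8
    if (is.finite(object@ltr) && object@ltr < 0)
        msg <- c(msg, "'ltr' must be nonnegative")
    if (is.finite(object@absP1) && object@absP1 < 0)
        msg <- c(msg, "'absP1' must be nonnegative")
    if (is.finite(object@tP1) && is.finite(object@tP2)) {
        if (object@tP1 < 1 || object@tP2 <= object@tP1)
            msg <- c(msg, "lags must satisfy t_P2 > t_P1 >= 1")
    }
    if (is.finite(object@ltr) && object@ltr > 0 && is.finite(object@normP1) &&
        abs(object@normP1 - object@absP1 / object@ltr) > tol)
        msg <- c(msg, "normP1 must equal absP1 / ltr")
    if (is.finite(object@ltr) && object@ltr > 0 && is.finite(object@normP2) &&
        abs(object@normP2 - object@p2 / object@ltr) > tol)
        msg <- c(msg, "normP2 must equal p2 / ltr")
    if (is.null(msg)) TRUE else msg
})

#' Scaled singular-value spectrum of a signal segment
#'
#' Singular values of a leads x samples segment, scaled so that the first
#' point equals the number of singular values K: y_i = K * sigma_i / sigma_1,
#' paired with indices x = 1..K. The scaling puts both axes in the same units
#' so that the distance-to-origin knee rule is geometrically meaningful.
#'
#' @slot x integer indices 1..K.
#' @slot y scaled singular values, non-increasing, y[1] = K.
#'
#' @seealso [scaledSpectrum()], [kneeDimension()]
#' @name ScaledSpectrum-class
#' @exportClass ScaledSpectrum
setClass("ScaledSpectrum", slots = c(x = "integer", y = "numeric"))

setValidity("ScaledSpectrum", function(object) {
    msg <- NULL
    K <- length(object@x)
    if (length(object@y) != K)
        msg <- c(msg, "'x' and 'y' must have equal length")
    else if (K > 0L) {
        if (!identical(object@x, seq_len(K)))
            msg <- c(msg, "'x' must be the indices 1..K")
        if (any(diff(object@y) > 1e-9))
            msg <- c(msg, "'y' must be non-increasing")
        if (any(object@y < 0))
            msg <- c(msg, "'y' must be nonnegative")
    }
    if (is.null(msg)) TRUE else msg
})

#' Spatial variability of AA propagation at two time scales
#'
#' Knee-based effective dimensions of signal segments: per-segment values and
#' their means at the short scale (segments of q samples, one AF cycle) and
#' the long scale (5-s segments).
#'
#' @slot sSvaap mean short-scale effective dimension.
#' @slot lSvaap mean long-scale effective dimension.
#' @slot perSegmentShort,perSegmentLong integer per-segment knee dimensions.
#' @slot q samples per short segment (round(fs / f_AF)).
#'
#' @seealso [svaap()], [shortSvaap()], [longSvaap()]
#' @name SvaapResult-class
#' @exportClass SvaapResult
setClass("SvaapResult",
    slots = c(sSvaap = "numeric", lSvaap = "numeric",
              perSegmentShort = "integer", perSegmentLong = "integer",
              q = "integer"))

setValidity("SvaapResult", function(object) {
    msg <- NULL
    chk <- function(agg, per, what) {
        if (length(per) && is.finite(agg) &&
            abs(agg - mean(per)) > 1e-8)
            paste0("'", what, "' must be the mean of its per-segment values")
        else NULL
    }
    msg <- c(msg, chk(object@sSvaap, object@perSegmentShort, "sSvaap"),
                  chk(object@lSvaap, object@perSegmentLong, "lSvaap"))
    if (any(object@perSegmentShort < 0L) || any(object@perSegmentLong < 0L))
        msg <- c(msg, "per-segment dimensions must be nonnegative")
    if (is.null(msg)) TRUE else msg
})

#' Parameters of the phenomenological pseudo-AA generator
#'
#' Governs the bounded-random-walk phase-modulation model: channel k of the
#' intrinsic signal is cos(2 pi f_AF / fs * n + s_k(n) + k / 2), where s_k is
#' a Gaussian random walk with per-step standard deviation v confined to
#' [-d, d]. The intrinsic channels are then mapped to `nLeads` surface leads
#' through a random linear map.
#'
#' @slot d phase bound in radians (range control).
#' @slot v standard deviation of the per-sample phase increment in radians
#'   (rate control).
#' @slot fAF dominant frequency in Hz.
#' @slot fs sampling rate in Hz.
#' @slot intrinsicDim number of intrinsic channels (model dimension).
#' @slot nLeads number of surface leads after the random linear map.
#' @slot nSamples number of time samples.
#' @slot sharedWalk if TRUE one walk drives all channels (planar-loop
#'   alternative); default FALSE, independent walks per channel.
#' @slot seed integer seed used by [simulateAA()]; NA to use the current RNG
#'   state.
#'
#' @seealso [modelParams()], [pseudoAA()], [simulateAA()]
#' @name ModelParams-class
#' @exportClass ModelParams
setClass("ModelParams",
    slots = c(d = "numeric", v = "numeric", fAF = "numeric", fs = "numeric",
              intrinsicDim = "integer", nLeads = "integer",
              nSamples = "integer", sharedWalk = "logical", seed = "integer"))

setValidity("ModelParams", function(object) {
    msg <- NULL
    if (object@d < 0) msg <- c(msg, "'d' must be nonnegative")
    if (object@v < 0) msg <- c(msg, "'v' must be nonnegative")
    if (object@fs <= 0) msg <- c(msg, "'fs' must be positive")
    if (object@fAF <= 0 || object@fAF >= object@fs / 2)
        msg <- c(msg, "'fAF' must lie in (0, fs/2)")
    if (object@intrinsicDim < 1L)
        msg <- c(msg, "'intrinsicDim' must be at least 1")
    if (object@nLeads < object@intrinsicDim)
        msg <- c(msg, "'nLeads' must be at least 'intrinsicDim'")
    if (object@nSamples < 1L)
        msg <- c(msg, "'nSamples' must be positive")
    if (is.null(msg)) TRUE else msg
})

#' Grid for model fitting
#'
#' Parameter grid for [fitSubject()]: candidate phase bounds d, increment
#' rates v, dominant-frequency offsets, and the number of model realisations
#' simulated per grid cell.
#'
#' @slot dValues candidate phase bounds (radians).
#' @slot vValues candidate increment standard deviations (radians).
#' @slot fafOffsets dominant-frequency perturbations (Hz) treated as a
#'   nuisance parameter; the cell score is the minimum over offsets.
#' @slot nModels model realisations per (d, v, offset) triple.
#'
#' @seealso [fitGrid()], [fitSubject()]
#' @name FitGrid-class
#' @exportClass FitGrid
setClass("FitGrid",
    slots = c(dValues = "numeric", vValues = "numeric",
              fafOffsets = "numeric", nModels = "integer"))

setValidity("FitGrid", function(object) {
    msg <- NULL
    if (!length(object@dValues) || !length(object@vValues) ||
        !length(object@fafOffsets))
        msg <- c(msg, "grid dimensions must be nonempty")
    if (object@nModels < 1L)
        msg <- c(msg, "'nModels' must be at least 1")
    if (is.null(msg)) TRUE else msg
})

#' Result of a grid-search model fit
#'
#' @slot bestD,bestV the minimising phase bound and increment rate.
#' @slot bestOffset dominant-frequency offset (Hz) chosen in the best cell.
#' @slot scoreSurface matrix of cell scores (rows = d, cols = v); each score
#'   is the minimum over offsets of the sum of absolute index differences.
#' @slot offsetSurface matrix of the offset attaining each cell score.
#' @slot grid the [FitGrid-class] used.
#'
#' @seealso [fitSubject()]
#' @name FitResult-class
#' @exportClass FitResult
setClass("FitResult",
    slots = c(bestD = "numeric", bestV = "numeric", bestOffset = "numeric",
              scoreSurface = "matrix", offsetSurface = "matrix",
              grid = "FitGrid"))

setValidity("FitResult", function(object) {
    msg <- NULL
    s <- object@scoreSurface
    if (all(!is.finite(s)))
        msg <- c(msg, "score surface has no valid cell")
    else {
        best <- s[match(object@bestD, object@grid@dValues),
                  match(object@bestV, object@grid@vValues)]
        if (!isTRUE(abs(best - min(s, na.rm = TRUE)) <= 1e-12))
            msg <- c(msg, "best cell must attain the surface minimum")
    }
    if (is.null(msg)) TRUE else msg
})

#' Dominant-frequency estimate
#'
#' Welch-periodogram dominant frequency per lead within a search band, and
#' their mean, used as the AF dominant frequency f_AF.
#'
#' @slot perLeadF per-lead peak frequency (Hz).
#' @slot fAF mean over leads (Hz).
#' @slot band search band (lo, hi) in Hz.
#' @slot edgeFlag TRUE when any per-lead peak sits on a band edge
#'   (band-limited estimate).
#' @slot reliable FALSE when the spectral peak is not well expressed relative
#'   to the band median power (e.g. broadband noise).
#'
#' @seealso [dominantFrequency()]
#' @name SpectralEstimate-class
#' @exportClass SpectralEstimate
setClass("SpectralEstimate",
    slots = c(perLeadF = "numeric", fAF = "numeric", band = "numeric",
              edgeFlag = "logical", reliable = "logical"))

setValidity("SpectralEstimate", function(object) {
    msg <- NULL
    if (length(object@band) != 2L || object@band[1L] >= object@band[2L])
        msg <- c(msg, "'band' must be (lo, hi) with lo < hi")
    else if (length(object@perLeadF)) {
        if (any(object@perLeadF < object@band[1L] - 1e-9) ||
            any(object@perLeadF > object@band[2L] + 1e-9))
            msg <- c(msg, "per-lead frequencies must lie within the band")
        if (abs(object@fAF - mean(object@perLeadF)) > 1e-9)
            msg <- c(msg, "'fAF' must be the mean of the per-lead estimates")
    }
    if (is.null(msg)) TRUE else msg
})
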