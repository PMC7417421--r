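#' Scaled singular-value spectrum of a segment
#'
#' Computes the singular values sigma_1 >= ... >= sigma_K of a leads x T
#' segment (K = min(leads, T)) and scales them by K / sigma_1, pairing each
#' with its index 1..K. The scaling puts both axes of the spectrum plot in
#' the same units, which makes the distance-to-origin knee rule meaningful
#' (analogous to picking the optimal operating point of an ROC curve).
#' Singular values below 1e-10 * sigma_1 are treated as exactly zero to
#' stabilise knee detection on rank-deficient segments.
#'
#' @param segment numeric leads x T matrix.
#' @param scaleCount `"auto"` (default) scales by K = min(leads, T);
#'   `"leads"` scales by the lead count even for segments shorter than the
#'   lead count.
#'
#' @return A [ScaledSpectrum-class].
#'
#' @examples
#' seg <- outer(1:6, sin(1:40))        # rank 1
#' scaledSpectrum(seg)@y               # (6, 0, 0, 0, 0, 0)
#' @export
scaledSpectrum <- function(segment, scaleCount = c("auto", "leads")) {
    scaleCount <- match.arg(scaleCount)
    segment <- as.matrix(segment)
    s <- svd(segment, nu = 0L, nv = 0L)$d
    if (!length(s) || s[1L] <= 0)
        stop("zero-energy segment")
    s[s < 1e-10 * s[1L]] <- 0
    K <- if (scaleCount == "leads") nrow(segment) else length(s)
    new("ScaledSpectrum", x = seq_along(s), y = s * K / s[1L])
}

#' Knee (effective) dimension of a scaled spectrum
#'
#' The knee index is the point of the scaled singular-value spectrum closest
#' to the origin: x* = argmin_x ||(x, y(x))||. That point marks the first
#' negligible singular value, so the effective dimension is x* - 1. Ties are
#' broken toward the smallest x. A result of 0 (closest point at x = 1, e.g.
#' a fully flat full-rank spectrum) indicates a degenerate spectrum.
#'
#' @param object a [ScaledSpectrum-class], or a numeric leads x T matrix from
#'   which the spectrum is computed first.
#' @param ... passed to [scaledSpectrum()] for the matrix method.
#'
#' @return Integer effective dimension in [0, K - 1].
#'
#' @examples
#' kneeDimension(outer(1:6, sin(1:40)))  # rank-1 segment -> 1
#' @name kneeDimension
NULL

#' @rdname kneeDimension
#' @export
setMethod("kneeDimension", "ScaledSpectrum", function(object, ...) {
    which.min(object@x^2 + object@y^2) - 1L
})

#' @rdname kneeDimension
#' @export
setMethod("kneeDimension", "matrix", function(object, ...) {
    kneeDimension(scaledSpectrum(object, ...))
})

# Split the sample axis into non-overlapping segments of segLen samples,
# discarding the remainder; returns a list of column index vectors.
.segmentIndex <- function(N, segLen) {
    nseg <- N %/% segLen
    lapply(seq_len(nseg), function(i) ((i - 1L) * segLen + 1L):(i * segLen))
}

#' Long-scale spatial variability of AA propagation
#'
#' l-SVAAP: the knee dimension of each non-overlapping 5-s segment of the
#' recording, averaged over segments. Long segments span many AF cycles, so
#' l-SVAAP captures how many spatial degrees of freedom AA propagation visits
#' over time scales where propagation patterns have reorganised repeatedly.
#'
#' @param x an [AASignalSet-class].
#' @param window segment length in seconds (default 5).
#' @param scaleCount passed to [scaledSpectrum()].
#'
#' @return A list with `lSvaap` (mean) and `perSegment` (integer vector).
#'
#' @examples
#' set.seed(1)
#' x <- randomControl(intrinsicDim = 5, nLeads = 20, nSamples = 2560)
#' longSvaap(x)$perSegment     # 5 for each 5-s segment
#' @export
longSvaap <- function(x, window = 5, scaleCount = "auto") {
    stopifnot(is(x, "AASignalSet"))
    segLen <- round(window * samplingRate(x))
    if (nSamples(x) < segLen)
        stop("signal too short for long-scale segments (need ", segLen,
             " samples)")
    d <- aaData(x)
    per <- vapply(.segmentIndex(ncol(d), segLen), function(idx)
        kneeDimension(scaledSpectrum(d[, idx, drop = FALSE],
                                     scaleCount = scaleCount)),
        integer(1L))
    list(lSvaap = mean(per), perSegment = per)
}

#' Short-scale spatial variability of AA propagation
#'
#' s-SVAAP: the knee dimension of each non-overlapping segment of
#' q = round(fs / f_AF) samples (about one AF cycle), averaged over segments.
#' Choosing the segment length from the dominant frequency adapts the short
#' scale to each subject's AF cycle length.
#'
#' @param x an [AASignalSet-class].
#' @param fAF AF dominant frequency in Hz; see [dominantFrequency()].
#' @param scaleCount passed to [scaledSpectrum()].
#'
#' @return A list with `sSvaap` (mean), `perSegment` (integer vector) and
#'   `q` (samples per segment).
#'
#' @examples
#' set.seed(1)
#' x <- randomControl(intrinsicDim = 5, nLeads = 20, nSamples = 1280)
#' shortSvaap(x, fAF = 6.5)$q  # 39 samples at 256 Hz
#' @export
shortSvaap <- function(x, fAF, scaleCount = "auto") {
    stopifnot(is(x, "AASignalSet"))
    fs <- samplingRate(x)
    if (fAF <= 0 || fAF >= fs / 2)
        stop("'fAF' must lie in (0, fs/2)")
    q <- as.integer(round(fs / fAF))
    if (q < 2L)
        stop("dominant frequency too high for segment analysis")
    if (nSamples(x) < q)
        stop("signal too short for one short-scale segment")
    d <- aaData(x)
    per <- vapply(.segmentIndex(ncol(d), q), function(idx)
        kneeDimension(scaledSpectrum(d[, idx, drop = FALSE],
                                     scaleCount = scaleCount)),
        integer(1L))
    list(sSvaap = mean(per), perSegment = per, q = q)
}

#' Spatial variability of AA propagation at both time scales
#'
#' Computes s-SVAAP and l-SVAAP for a recording and returns them in a single
#' [SvaapResult-class]. For persistent AF (and for the phenomenological
#' model) l-SVAAP is expected to exceed s-SVAAP: propagation patterns are
#' more self-similar within one AF cycle than across many.
#'
#' @param x an [AASignalSet-class].
#' @param fAF AF dominant frequency in Hz (e.g. from [dominantFrequency()]).
#' @param longWindow long-segment length in seconds (default 5).
#' @param scaleCount passed to [scaledSpectrum()].
#'
#' @return A [SvaapResult-class].
#'
#' @examples
#' set.seed(1)
#' x <- simulateAA(modelParams(nSamples = 2560, nLeads = 32))
#' svaap(x, fAF = 6.5)
#' @export
svaap <- function(x, fAF, longWindow = 5, scaleCount = "auto") {
    s <- shortSvaap(x, fAF = fAF, scaleCount = scaleCount)
    l <- longSvaap(x, window = longWindow, scaleCount = scaleCount)
    new("SvaapResult", sSvaap = s$sSvaap, lSvaap = l$lSvaap,
        perSegmentShort = s$perSegment, perSegmentLong = l$perSegment,
        q = s$q)
}
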