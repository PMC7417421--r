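# Apply a zero-phase (forward-backward) IIR filter to every lead. Each lead
# is extended by odd reflection at both ends before filtering so that filter
# start-up transients decay inside the padding, not in the signal.
.filtfiltRows <- function(filt, x) {
    d <- aaData(x)
    N <- ncol(d)
    pad <- min(N - 1L, as.integer(3 * samplingRate(x)))
    out <- t(apply(d, 1L, function(row) {
        ext <- c(2 * row[1L] - row[(pad + 1L):2L],
                 row,
                 2 * row[N] - row[(N - 1L):(N - pad)])
        signal::filtfilt(filt, ext)[(pad + 1L):(pad + N)]
    }))
    AASignalSet(out, fs = samplingRate(x), leadIds = leadIds(x))
}

#' Band-pass pre-filter (1-100 Hz)
#'
#' 3rd-order Chebyshev type-I band-pass (0.5 dB passband ripple) applied
#' forward-backward (zero phase). Removes DC/baseline drift below the lower
#' edge and high-frequency noise above the upper edge.
#'
#' @param x an [AASignalSet-class].
#' @param low,high band edges in Hz (defaults 1 and 100).
#' @param order filter order (default 3).
#' @param ripple passband ripple in dB (default 0.5).
#'
#' @return A filtered [AASignalSet-class].
#' @export
bandpassAA <- function(x, low = 1, high = 100, order = 3L, ripple = 0.5) {
    fs <- samplingRate(x)
    if (fs <= 2 * high)
        stop("sampling rate too low for the requested upper band edge")
    filt <- signal::cheby1(order, ripple, c(low, high) / (fs / 2),
                           type = "pass")
    .filtfiltRows(filt, x)
}

#' Power-line notch filter
#'
#' Zero-phase 2nd-order IIR notch, unit gain away from the notch frequency.
#' Default 50 Hz with a 1 Hz -3 dB bandwidth.
#'
#' @param x an [AASignalSet-class].
#' @param freq notch frequency in Hz (default 50).
#' @param bw notch bandwidth in Hz (default 1).
#'
#' @return A filtered [AASignalSet-class].
#' @export
notchAA <- function(x, freq = 50, bw = 1) {
    fs <- samplingRate(x)
    if (freq <= 0 || freq >= fs / 2)
        stop("'freq' must lie in (0, fs/2)")
    w0 <- 2 * pi * freq / fs
    r <- exp(-pi * bw / fs)
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1, -2 * r * cos(w0), r^2)
    b <- b * sum(a) / sum(b)  # unit gain at DC
    .filtfiltRows(signal::Arma(b = b, a = a), x)
}

#' High-pass pre-filter (3 Hz)
#'
#' 3rd-order Chebyshev type-I high-pass (0.5 dB ripple) applied
#' forward-backward, removing low-frequency residuals below the AF band.
#'
#' @param x an [AASignalSet-class].
#' @param cutoff cutoff frequency in Hz (default 3).
#' @param order filter order (default 3).
#' @param ripple passband ripple in dB (default 0.5).
#'
#' @return A filtered [AASignalSet-class].
#' @export
highpassAA <- function(x, cutoff = 3, order = 3L, ripple = 0.5) {
    fs <- samplingRate(x)
    if (cutoff <= 0 || cutoff >= fs / 2)
        stop("'cutoff' must lie in (0, fs/2)")
    filt <- signal::cheby1(order, ripple, cutoff / (fs / 2), type = "high")
    .filtfiltRows(filt, x)
}

#' Standard AA pre-filtering chain
#'
#' Applies, in order: 1-100 Hz band-pass, 50 Hz notch, 3 Hz high-pass — the
#' pre-filters expected upstream of recurrence and SVAAP analysis. Inputs are
#' assumed to be atrial-activity-only signals (ventricular activity removed
#' upstream, or synthetic).
#'
#' @param x an [AASignalSet-class].
#' @param notchFreq power-line frequency in Hz (default 50).
#'
#' @return A filtered [AASignalSet-class].
#' @export
preprocessAA <- function(x, notchFreq = 50) {
    highpassAA(notchAA(bandpassAA(x), freq = notchFreq))
}

# Welch power spectral density of one lead: Hamming-windowed segments of
# nwin samples with the given overlap, mean-removed, periodograms averaged.
.welchPsd <- function(sig, nwin, overlapFrac) {
    step <- max(1L, round(nwin * (1 - overlapFrac)))
    starts <- seq(1L, length(sig) - nwin + 1L, by = step)
    w <- signal::hamming(nwin)
    P <- numeric(nwin)
    for (s0 in starts) {
        seg <- sig[s0:(s0 + nwin - 1L)]
        seg <- (seg - mean(seg)) * w
        P <- P + Mod(fft(seg))^2
    }
    P / length(starts)
}

#' Dominant-frequency estimation
#'
#' Estimates the AF dominant frequency per lead as the location of the Welch
#' periodogram maximum within a search band (default 3-12 Hz, 4-s Hamming
#' windows with 50% overlap), and averages over leads. The estimate is
#' flagged `edgeFlag` when any per-lead peak falls on a band edge
#' (band-limited estimate) and `reliable = FALSE` when the peak is weakly
#' expressed relative to the median in-band power (broadband signals).
#'
#' @param x an [AASignalSet-class] with at least 4 s of signal.
#' @param band search band (lo, hi) in Hz.
#' @param windowSec Welch window length in seconds (default 4).
#' @param overlapFrac window overlap fraction (default 0.5).
#' @param minPeakRatio peak-to-median power ratio below which the estimate is
#'   flagged unreliable (default 3).
#'
#' @return A [SpectralEstimate-class].
#'
#' @examples
#' n <- 0:2047
#' x <- AASignalSet(rbind(cos(2 * pi * 6 * n / 256),
#'                        sin(2 * pi * 6 * n / 256)), fs = 256)
#' dominantFrequency(x)@fAF   # 6 Hz
#' @export
dominantFrequency <- function(x, band = c(3, 12), windowSec = 4,
                              overlapFrac = 0.5, minPeakRatio = 3) {
    fs <- samplingRate(x)
    nwin <- round(windowSec * fs)
    if (nSamples(x) < nwin)
        stop("signal too short for spectral estimation (need ", nwin,
             " samples)")
    freqs <- (0:(nwin - 1L)) * fs / nwin
    inBand <- which(freqs >= band[1L] & freqs <= band[2L])
    if (length(inBand) < 3L)
        stop("search band too narrow for the spectral resolution")
    d <- aaData(x)
    perLead <- numeric(nrow(d))
    edge <- FALSE
    ratios <- numeric(nrow(d))
    for (k in seq_len(nrow(d))) {
        P <- .welchPsd(d[k, ], nwin, overlapFrac)[inBand]
        imax <- which.max(P)
        perLead[k] <- freqs[inBand[imax]]
        ratios[k] <- P[imax] / stats::median(P)
        if (imax == 1L || imax == length(inBand)) edge <- TRUE
    }
    new("SpectralEstimate", perLeadF = perLead, fAF = mean(perLead),
        band = as.numeric(band), edgeFlag = edge,
        reliable = stats::median(ratios) >= minPeakRatio)
}
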