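#' Partition a recording into non-overlapping analysis blocks
#'
#' Splits the sample axis into consecutive non-overlapping blocks of 2M
#' columns each; trailing columns that do not fill a block are discarded.
#' Within each block an M x M recurrence matrix can be formed, so that lags
#' 0..M-1 are available for every reference time point.
#'
#' @param x an [AASignalSet-class] or a leads x samples numeric matrix.
#' @param M analysis window size in samples (default 500, about 2 s at
#'   256 Hz; each block spans 2M samples).
#'
#' @return A list of leads x 2M matrices, one per block.
#'
#' @examples
#' x <- AASignalSet(matrix(rnorm(2 * 4000), 2), fs = 256)
#' length(partitionBlocks(x, M = 500))  # 4 blocks of 1000 samples
#' @export
partitionBlocks <- function(x, M = 500L) {
    d <- if (is(x, "AASignalSet")) aaData(x) else as.matrix(x)
    M <- as.integer(M)
    if (M < 1L)
        stop("'M' must be a positive integer")
    N <- ncol(d)
    if (N < 2L * M)
        stop("signal too short for one block (need ", 2L * M,
             " samples, have ", N, ")")
    nb <- N %/% (2L * M)
    lapply(seq_len(nb), function(m)
        d[, ((m - 1L) * 2L * M + 1L):(m * 2L * M), drop = FALSE])
}

# Columns scaled to unit Euclidean norm; errors on zero-norm columns.
.normalizeColumns <- function(block) {
    nrm <- sqrt(.colSums(block^2, nrow(block), ncol(block)))
    bad <- which(nrm == 0 | !is.finite(nrm))
    if (length(bad))
        stop("degenerate sample vector (zero norm) at column ", bad[1L])
    block / rep(nrm, each = nrow(block))
}

#' Recurrence matrix of one analysis block
#'
#' Computes the M x M matrix of cosine similarities between spatial AA
#' vectors: entry (i, j) is the cosine of the angle between column i and
#' column i + j - 1 of the block, so that column j holds lag p = j - 1.
#' The normalisation by the column norms makes the matrix sensitive to the
#' shape of the spatial profiles only, not their amplitude.
#'
#' @param block a leads x 2M numeric matrix (one element of
#'   [partitionBlocks()]).
#' @param blockIndex 1-based index of the block, stored for bookkeeping.
#'
#' @return A [RecurrenceMatrix-class]; entries lie in [-1, 1] and the first
#'   column is identically 1.
#'
#' @examples
#' b <- rbind(cos(2 * pi * 8 * (0:99) / 256), sin(2 * pi * 8 * (0:99) / 256))
#' R <- recurrenceMatrix(b)
#' dim(R@values)  # 50 x 50
#' @export
recurrenceMatrix <- function(block, blockIndex = 1L) {
    block <- as.matrix(block)
    M <- ncol(block) %/% 2L
    if (M < 1L)
        stop("block must have at least 2 columns")
    U <- .normalizeColumns(block)
    G <- crossprod(U[, seq_len(M), drop = FALSE], U)  # M x 2M
    i <- seq_len(M)
    idx <- cbind(rep(i, times = M), rep(i, times = M) +
                 rep(0L:(M - 1L), each = M))
    vals <- matrix(G[idx], nrow = M, ncol = M)
    vals[vals > 1] <- 1
    vals[vals < -1] <- -1
    new("RecurrenceMatrix", values = vals, blockIndex = as.integer(blockIndex))
}

#' Multi-variable AA recurrence signal
#'
#' The recurrence signal r(p) is the mean over reference times i of the
#' cosine similarity at lag p: the column means of the block's recurrence
#' matrix. It is a multi-variable autocorrelation of the spatial AA patterns,
#' with r(0) = 1 and |r(p)| <= 1.
#'
#' The matrix method averages an existing [RecurrenceMatrix-class]; the
#' matrix-block method computes r(p) directly from a leads x 2M block without
#' materialising the M x M matrix.
#'
#' @param object a [RecurrenceMatrix-class] or a leads x 2M numeric block.
#' @param blockIndex block index recorded in the result (block method only).
#' @param ... unused.
#'
#' @return A [RecurrenceSignal-class] with lags p = 0..M-1.
#'
#' @examples
#' n <- 0:199
#' b <- rbind(cos(2 * pi * 8 * n / 256), sin(2 * pi * 8 * n / 256))
#' r <- recurrenceSignal(b)
#' r@r[1]   # 1 at lag 0
#' @name recurrenceSignal
NULL

#' @rdname recurrenceSignal
#' @export
setMethod("recurrenceSignal", "RecurrenceMatrix", function(object, ...) {
    new("RecurrenceSignal", r = colMeans(object@values),
        blockIndex = object@blockIndex)
})

#' @rdname recurrenceSignal
#' @export
setMethod("recurrenceSignal", "matrix",
    function(object, blockIndex = 1L, ...) {
    M <- ncol(object) %/% 2L
    if (M < 1L)
        stop("block must have at least 2 columns")
    # r(p) = (1/M) sum_{i<=M} sum_c U[c,i] U[c,i+p]: a sum of per-channel
    # linear cross-correlations, evaluated by FFT over the 2M-sample block
    # (the first factor is zero-padded, so no circular wrap-around occurs
    # for lags 0..M-1)
    U <- .normalizeColumns(object[, seq_len(2L * M), drop = FALSE])
    A <- t(U)                                   # time x channels
    Ahead <- A
    Ahead[(M + 1L):(2L * M), ] <- 0
    s <- rowSums(Conj(stats::mvfft(Ahead)) * stats::mvfft(A))
    r <- Re(stats::fft(s, inverse = TRUE))[seq_len(M)] / (2L * M * M)
    r[r > 1] <- 1
    r[r < -1] <- -1
    r[1L] <- 1
    new("RecurrenceSignal", r = r, blockIndex = as.integer(blockIndex))
})

#' Recurrence signals for all blocks of a recording
#'
#' Convenience wrapper: partitions the recording into blocks of 2M samples
#' and computes one [RecurrenceSignal-class] per block.
#'
#' @inheritParams partitionBlocks
#' @return A list of [RecurrenceSignal-class] objects.
#' @seealso [partitionBlocks()], [recurrenceSignal()], [subjectIndices()]
#' @export
recurrenceSignals <- function(x, M = 500L) {
    blocks <- partitionBlocks(x, M)
    lapply(seq_along(blocks), function(m)
        recurrenceSignal(blocks[[m]], blockIndex = m))
}

# First qualifying extremum of r at lag >= start (0-based lags).
# sign = -1 searches a local minimum, +1 a local maximum. Plateaus are
# resolved to their first lag; endpoints never qualify. Returns NA if none.
.firstExtremum <- function(r, start, sign) {
    n <- length(r)
    rle_ <- rle(r)
    vals <- rle_$values
    firsts <- cumsum(c(0L, head(rle_$lengths, -1L)))  # 0-based first lag
    k <- length(vals)
    if (k < 3L) return(NA_integer_)
    for (j in 2L:(k - 1L)) {
        if (firsts[j] < start) next
        if (sign * (vals[j] - vals[j - 1L]) > 0 &&
            sign * (vals[j] - vals[j + 1L]) > 0)
            return(firsts[j])
    }
    NA_integer_
}

#' Short-term peaks of a recurrence signal
#'
#' Locates the first negative peak (first strict local minimum at lag >= 1)
#' and the first positive peak (first strict local maximum after it). For an
#' oscillation with dominant frequency f, the first negative peak is expected
#' near half a period (Fs / 2f samples) and the first positive peak near a
#' full period (Fs / f samples). Plateaus are resolved to their first lag; no
#' smoothing is applied.
#'
#' @param r a [RecurrenceSignal-class] or a numeric vector of lagged
#'   recurrence values (element p + 1 = lag p).
#'
#' @return A list with `absP1`, `tP1`, `p2`, `tP2` and a logical `ok`. When
#'   no qualifying extremum exists (`ok = FALSE`) the values are NA and the
#'   block should be excluded from index aggregation.
#'
#' @examples
#' r <- cos(2 * pi * 8 * (0:499) / 256)
#' shortTermPeaks(r)[c("tP1", "tP2")]  # 16 and 32 samples
#' @export
shortTermPeaks <- function(r) {
    if (is(r, "RecurrenceSignal")) r <- r@r
    if (length(r) < 3L)
        stop("recurrence signal too short for peak detection")
    t1 <- .firstExtremum(r, start = 1L, sign = -1L)
    if (is.na(t1))
        return(list(absP1 = NA_real_, tP1 = NA_integer_, p2 = NA_real_,
                    tP2 = NA_integer_, ok = FALSE))
    t2 <- .firstExtremum(r, start = t1 + 1L, sign = +1L)
    if (is.na(t2))
        return(list(absP1 = abs(r[t1 + 1L]), tP1 = t1, p2 = NA_real_,
                    tP2 = NA_integer_, ok = FALSE))
    list(absP1 = abs(r[t1 + 1L]), tP1 = t1, p2 = r[t2 + 1L], tP2 = t2,
         ok = TRUE)
}

#' Long-term recurrence over a lag band
#'
#' LTR is the average over blocks of the mean absolute recurrence within a
#' fixed lag band (default lags 150..450, i.e. roughly 0.6-1.8 s at 256 Hz,
#' where recurrence-signal envelopes have reached their plateau). It
#' quantifies the long-term recurrent behaviour of AA propagation.
#'
#' @param blocksR a list of [RecurrenceSignal-class] objects (or numeric
#'   vectors), one per block.
#' @param lo,hi lag band limits in samples (inclusive).
#'
#' @return LTR, a value in [0, 1].
#'
#' @examples
#' r1 <- c(1, rep(0.2, 500)); r2 <- c(1, rep(0.4, 500))
#' ltrFromBlocks(list(r1, r2))  # 0.3
#' @export
ltrFromBlocks <- function(blocksR, lo = 150L, hi = 450L) {
    if (!length(blocksR))
        stop("at least one block is required")
    vals <- vapply(blocksR, function(r) {
        if (is(r, "RecurrenceSignal")) r <- r@r
        if (length(r) <= hi)
            stop("window too short for LTR band (need lags up to ", hi, ")")
        mean(abs(r[(lo + 1L):(hi + 1L)]))
    }, numeric(1L))
    mean(vals)
}

#' Subject-level recurrence indices
#'
#' Aggregates the block-wise recurrence signals of one subject into the
#' characteristic indices: per-block short-term peaks are averaged over the
#' non-degenerate blocks (arithmetic mean), LTR is computed over all blocks,
#' and the peak amplitudes are divided by LTR to give the normalised indices
#' that remove the influence of the overall substrate complexity on the
#' short-term behaviour.
#'
#' @param object an [AASignalSet-class] (blocks and recurrence signals are
#'   computed internally) or a list of [RecurrenceSignal-class] objects.
#' @param M analysis window size (AASignalSet method).
#' @param lo,hi LTR lag band, passed to [ltrFromBlocks()].
#' @param ... unused.
#'
#' @return A [RecurrenceIndices-class].
#'
#' @examples
#' set.seed(1)
#' x <- simulateAA(modelParams(nSamples = 4000))
#' subjectIndices(x)
#' @name subjectIndices
NULL

#' @rdname subjectIndices
#' @export
setMethod("subjectIndices", "list", function(object, lo = 150L, hi = 450L,
                                             ...) {
    peaks <- lapply(object, shortTermPeaks)
    ok <- vapply(peaks, `[[`, logical(1L), "ok")
    if (!any(ok))
        stop("no indices computable: all blocks degenerate")
    mean_of <- function(f) mean(vapply(peaks[ok], `[[`, numeric(1L), f))
    ltr <- ltrFromBlocks(object, lo = lo, hi = hi)
    absP1 <- mean_of("absP1")
    p2 <- mean_of("p2")
    if (ltr > 0) {
        normP1 <- absP1 / ltr
        normP2 <- p2 / ltr
    } else {
        warning("LTR is zero: normalised indices undefined")
        normP1 <- NA_real_
        normP2 <- NA_real_
    }
    new("RecurrenceIndices", ltr = ltr, absP1 = absP1, p2 = p2,
        tP1 = mean_of("tP1"), tP2 = mean_of("tP2"),
        normP1 = normP1, normP2 = normP2,
        nBlocks = length(object), nDegenerate = sum(!ok))
})

#' @rdname subjectIndices
#' @export
setMethod("subjectIndices", "AASignalSet",
    function(object, M = 500L, lo = 150L, hi = 450L, ...) {
    subjectIndices(recurrenceSignals(object, M = M), lo = lo, hi = hi)
})

#' Flat data.frame view of recurrence indices
#'
#' @param indices a [RecurrenceIndices-class].
#' @param subject optional subject label prepended as a column.
#' @return A one-row data.frame with columns `p1_abs`, `t_p1`, `p2`, `t_p2`,
#'   `ltr`, `norm_p1`, `norm_p2`, `n_blocks`, `n_degenerate`.
#' @export
indicesToDataFrame <- function(indices, subject = NULL) {
    df <- data.frame(p1_abs = indices@absP1, t_p1 = indices@tP1,
                     p2 = indices@p2, t_p2 = indices@tP2, ltr = indices@ltr,
                     norm_p1 = indices@normP1, norm_p2 = indices@normP2,
                     n_blocks = indices@nBlocks,
                     n_degenerate = indices@nDegenerate)
    if (!is.null(subject)) df <- cbind(subject = subject, df)
    df
}
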